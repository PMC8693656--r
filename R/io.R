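#' Read an expression matrix from disk
#'
#' Dense TSV input has gene symbols in the first column and sample/cell
#' identifiers in the header; Matrix Market input is a coordinate `.mtx`
#' file (1-based indices, per the format standard) plus row-name and
#' column-name sidecar files, one symbol/identifier per line. Duplicate
#' gene rows are collapsed by summation with a warning; duplicate column
#' identifiers are an error.
#'
#' @param path path to the TSV or `.mtx` file.
#' @param format `"dense-tsv"` or `"matrix-market"`.
#' @param genes_path,cols_path sidecar paths for matrix-market input;
#'   default to `genes.tsv` and `cells.tsv` next to the `.mtx` file.
#' @param scale declared expression scale of the file (default raw counts).
#' @param role column role tag (default `"single-cell"`).
#' @return an [expression_matrix()].
#' @export
read_expression <- function(path, format = c("dense-tsv", "matrix-market"),
                            genes_path = NULL, cols_path = NULL,
                            scale = "counts", role = "single-cell") {
  format <- match.arg(format)
  if (!file.exists(path))
    pm_data_error(paste0("read_expression: no such file: ", path))
  if (format == "dense-tsv") {
    df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                            stringsAsFactors = FALSE)
    if (ncol(df) < 2)
      pm_data_error(paste0(path, ": expected gene column plus >=1 sample column"))
    ids <- colnames(df)[-1]
    if (anyDuplicated(ids))
      pm_data_error(paste0(path, ": duplicate column names: ",
                           paste(unique(ids[duplicated(ids)]), collapse = ", ")))
    vals <- df[, -1, drop = FALSE]
    for (j in seq_along(vals)) {
      v <- vals[[j]]
      if (!is.numeric(v)) {
        bad <- which(is.na(suppressWarnings(as.numeric(v))))[1]
        pm_data_error(sprintf(
          "%s: non-numeric value in column '%s', line %d",
          path, ids[j], bad + 1L))
      }
      if (anyNA(v))
        pm_data_error(sprintf("%s: missing value in column '%s', line %d",
                              path, ids[j], which(is.na(v))[1] + 1L))
    }
    mat <- as.matrix(vals)
    rownames(mat) <- df[[1]]
  } else {
    dir <- dirname(path)
    genes_path <- genes_path %||% file.path(dir, "genes.tsv")
    cols_path <- cols_path %||% file.path(dir, "cells.tsv")
    for (f in c(genes_path, cols_path))
      if (!file.exists(f))
        pm_data_error(paste0("read_expression: missing sidecar file: ", f))
    m <- as.matrix(Matrix::readMM(path))
    rn <- readLines(genes_path)
    cn <- readLines(cols_path)
    if (length(rn) != nrow(m))
      pm_data_error(sprintf(
        "%s: header says %d rows but %s has %d lines",
        path, nrow(m), genes_path, length(rn)))
    if (length(cn) != ncol(m))
      pm_data_error(sprintf(
        "%s: header says %d columns but %s has %d lines",
        path, ncol(m), cols_path, length(cn)))
    if (anyDuplicated(cn))
      pm_data_error(paste0(path, ": duplicate column identifiers in sidecar"))
    dimnames(m) <- list(rn, cn)
    mat <- m
  }
  if (anyDuplicated(rownames(mat))) {
    dups <- unique(rownames(mat)[duplicated(rownames(mat))])
    warning(sprintf("%s: %d duplicated gene symbol(s) collapsed by summation: %s",
                    path, length(dups),
                    paste(utils::head(dups, 5), collapse = ", ")))
    mat <- rowsum(mat, group = rownames(mat), reorder = FALSE)
  }
  expression_matrix(mat, scale = scale, role = role)
}

#' Write an expression matrix to disk
#'
#' Dense TSV is written with `%.10g` precision so that the
#' read/write pair round-trips losslessly; matrix-market output writes the
#' `.mtx` plus `genes.tsv` and `cells.tsv` sidecars. UNIX newlines, UTF-8.
#'
#' @param expr an [expression_matrix()].
#' @param path output path (`.tsv` or `.mtx`).
#' @param format `"dense-tsv"` or `"matrix-market"`.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path,
                             format = c("dense-tsv", "matrix-market")) {
  format <- match.arg(format)
  if (!inherits(expr, "expr_matrix"))
    pm_data_error("write_expression: input must be an expr_matrix")
  if (format == "dense-tsv") {
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(paste(c("gene", colnames(expr)), collapse = "\t"), con)
    body <- apply(unclass(expr), 1, function(r)
      paste(sprintf("%.10g", r), collapse = "\t"))
    writeLines(paste(rownames(expr), body, sep = "\t"), con)
  } else {
    dir <- dirname(path)
    Matrix::writeMM(Matrix::Matrix(unclass(expr), sparse = TRUE), path)
    writeLines(rownames(expr), file.path(dir, "genes.tsv"))
    writeLines(colnames(expr), file.path(dir, "cells.tsv"))
  }
  invisible(path)
}

#' Gene set constructor
#'
#' An ordered collection of unique gene symbols with a name, a species tag
#' and the intended size `k` (the realized size may fall short when the
#' source matrix lacked symbols; the deficit is the caller's to log).
#'
#' @param name set name.
#' @param members ordered gene symbols; duplicates are rejected.
#' @param species species tag, e.g. `"mouse"` or `"human"`.
#' @param k intended size (defaults to `length(members)`).
#' @return a `gene_set` object.
#' @export
gene_set <- function(name, members, species = "mouse", k = length(members)) {
  members <- as.character(members)
  if (anyDuplicated(members))
    pm_data_error(paste0("gene_set '", name, "': duplicate members"))
  if (length(members) == 0)
    pm_data_error(paste0("gene_set '", name, "': empty set"))
  structure(list(name = name, members = members, species = species,
                 k = as.integer(k)),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %s [%s], %d genes: %s%s\n", x$name, x$species,
              length(x$members),
              paste(utils::head(x$members, 6), collapse = ", "),
              if (length(x$members) > 6) ", ..." else ""))
  invisible(x)
}

#' Read gene sets from a GMT file
#'
#' One set per line: name, description, then member symbols, tab-separated.
#' Duplicate members within a set are dropped (first occurrence kept) with
#' a warning; a line with fewer than three fields is a parse error.
#'
#' @param path GMT file path.
#' @param species species tag to attach to every set (GMT carries none).
#' @return a named list of [gene_set()] objects.
#' @export
read_gmt <- function(path, species = "mouse") {
  if (!file.exists(path))
    pm_data_error(paste0("read_gmt: no such file: ", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3)
      pm_data_error(sprintf("%s: line %d has %d field(s); need name, description, >=1 member",
                            path, i, length(fields)))
    members <- fields[-(1:2)]
    if (anyDuplicated(members)) {
      warning(sprintf("%s: line %d ('%s'): duplicated members de-duplicated",
                      path, i, fields[1]))
      members <- members[!duplicated(members)]
    }
    sets[[i]] <- gene_set(fields[1], members, species = species)
  }
  names(sets) <- vapply(sets, `[[`, "", "name")
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets a [gene_set()] or list of them.
#' @param path output path.
#' @param description description field written for each set (default "na").
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = "na") {
  if (inherits(sets, "gene_set")) sets <- list(sets)
  lines <- vapply(sets, function(s)
    paste(c(s$name, description, s$members), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a surface-molecule annotation table
#'
#' TSV with header and columns `symbol` and `is_surface` (0/1). Which
#' genes count as "surface molecule-encoding" is a curation decision this
#' file externalizes; the package never hard-codes a surface universe.
#'
#' @param path TSV path.
#' @param provenance free-text provenance recorded on the object.
#' @return a `surface_annotation`: data.frame `symbol`, `is_surface`
#'   (logical), with a `provenance` attribute.
#' @export
read_surface_annotation <- function(path, provenance = path) {
  if (!file.exists(path))
    pm_data_error(paste0("read_surface_annotation: no such file: ", path))
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("symbol", "is_surface")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    pm_data_error(paste0(path, ": missing required column(s): ",
                         paste(miss, collapse = ", ")))
  if (!all(df$is_surface %in% c(0, 1)))
    pm_data_error(paste0(path, ": is_surface must be 0 or 1; offending line ",
                         which(!df$is_surface %in% c(0, 1))[1] + 1L))
  if (anyDuplicated(df$symbol))
    pm_data_error(paste0(path, ": duplicate symbols in annotation"))
  surface_annotation(df$symbol, as.logical(df$is_surface), provenance)
}

#' @rdname read_surface_annotation
#' @param symbols gene symbols.
#' @param is_surface logical flags, same length.
#' @export
surface_annotation <- function(symbols, is_surface, provenance = "in-memory") {
  out <- data.frame(symbol = as.character(symbols),
                    is_surface = as.logical(is_surface),
                    stringsAsFactors = FALSE)
  attr(out, "provenance") <- provenance
  class(out) <- c("surface_annotation", "data.frame")
  out
}

#' Read an ortholog symbol table
#'
#' TSV with header and columns `source_symbol`, `target_symbol`,
#' `source_species`, `target_species`. Many-to-many mappings are allowed
#' at load time; species tags must come from the controlled vocabulary.
#'
#' @param path TSV path.
#' @param species_vocabulary allowed species tags.
#' @return an `ortholog_table` data.frame.
#' @export
read_ortholog_table <- function(path,
                                species_vocabulary = c("mouse", "human")) {
  if (!file.exists(path))
    pm_data_error(paste0("read_ortholog_table: no such file: ", path))
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("source_symbol", "target_symbol", "source_species", "target_species")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    pm_data_error(paste0(path, ": missing required column(s): ",
                         paste(miss, collapse = ", ")))
  if (any(!nzchar(df$source_symbol)) || any(!nzchar(df$target_symbol)))
    pm_data_error(paste0(path, ": empty symbol; offending line ",
                         which(!nzchar(df$source_symbol) |
                                 !nzchar(df$target_symbol))[1] + 1L))
  bad <- !(df$source_species %in% species_vocabulary &
             df$target_species %in% species_vocabulary)
  if (any(bad))
    pm_data_error(sprintf(
      "%s: species outside vocabulary {%s}; offending line %d",
      path, paste(species_vocabulary, collapse = ", "), which(bad)[1] + 1L))
  class(df) <- c("ortholog_table", "data.frame")
  df
}

#' Write the surface annotation emitted by the simulator
#' @param ann data.frame with `symbol` and `is_surface` columns.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_surface_annotation <- function(ann, path) {
  utils::write.table(
    data.frame(symbol = ann$symbol, is_surface = as.integer(ann$is_surface)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
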