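#' Derive a population signature gene set from bulk expression
#'
#' Ranks genes by the mean log2(TPM + 1) difference between two labeled
#' bulk populations (i.e. the log2 fold change on the log scale),
#' descending, and returns the top `k` as the signature of `pop_a`.
#' Calling with the labels swapped yields the signature of the other
#' population. Genes whose mean in `pop_a` falls below `min_mean` are
#' ineligible. Ties are broken by larger `pop_a` mean, then by symbol.
#'
#' @param bulk an [expression_matrix()] on the log2(TPM + 1) scale whose
#'   column names start with the population labels (e.g. `POP_A_rep1`), or
#'   exactly equal them.
#' @param pop_a,pop_b population labels; the signature is for `pop_a`.
#' @param k signature size (10 for the discovery sets, 200 for the
#'   validation sets).
#' @param min_mean eligibility floor on the `pop_a` mean (default 0 = off;
#'   bulk noise at near-zero genes can corrupt top-k ranking, so a floor
#'   is available).
#' @param species species tag for the resulting set.
#' @return a [gene_set()] of size `k` in rank order.
#' @export
derive_signature <- function(bulk, pop_a, pop_b, k = 10, min_mean = 0,
                             species = "mouse") {
  if (!inherits(bulk, "expr_matrix") || expr_scale(bulk) != "log2tpm")
    pm_data_error("derive_signature: bulk must be an expr_matrix on the log2(TPM+1) scale")
  if (k < 1) pm_config_error("derive_signature: k must be >= 1")
  cols_of <- function(label) {
    hit <- colnames(bulk) == label | startsWith(colnames(bulk), paste0(label, "_"))
    if (!any(hit))
      pm_config_error(paste0("derive_signature: unknown population label: ", label))
    which(hit)
  }
  ia <- cols_of(pop_a); ib <- cols_of(pop_b)
  mean_a <- rowMeans(bulk[, ia, drop = FALSE])
  mean_b <- rowMeans(bulk[, ib, drop = FALSE])
  delta <- mean_a - mean_b
  eligible <- mean_a >= min_mean
  if (sum(eligible) < k)
    pm_config_error(sprintf(
      "derive_signature: k=%d but only %d eligible gene(s) (shortfall %d)",
      k, sum(eligible), k - sum(eligible)))
  if (all(delta[eligible] == delta[eligible][1]))
    warning("derive_signature: all eligible genes tied; ranking is by mean then symbol")
  ord <- order(-delta, -mean_a, rownames(bulk))
  ord <- ord[eligible[ord]]
  gene_set(paste0(pop_a, "_signature_top", k),
           rownames(bulk)[ord[seq_len(k)]], species = species, k = k)
}

#' Per-gene Z-scores across cells
#'
#' Standardizes each gene across all cells: `z = (x - mean) / sd` with the
#' sample (n-1) standard deviation. A gene with zero variance carries no
#' between-cell information and maps to all-zero. This per-gene
#' orientation is what makes a per-cell *sum* of Z-scores over a signature
#' well defined.
#'
#' @param sc an [expression_matrix()] on the log2(TPM + 1) scale with at
#'   least 2 cells.
#' @return a numeric matrix of the same shape and dimnames.
#' @export
zscore_by_gene <- function(sc) {
  if (!inherits(sc, "expr_matrix") || expr_scale(sc) != "log2tpm")
    pm_data_error("zscore_by_gene: input must be an expr_matrix on the log2(TPM+1) scale")
  if (ncol(sc) < 2)
    pm_numeric_error("zscore_by_gene: need >= 2 cells")
  x <- unclass(sc)
  mu <- rowMeans(x)
  sd_ <- sqrt(rowSums((x - mu)^2) / (ncol(x) - 1L))
  z <- (x - mu) / ifelse(sd_ == 0, 1, sd_)
  z[sd_ == 0, ] <- 0
  z
}

#' Score cells by the summed Z-score of a gene set
#'
#' The per-cell score is the sum over the set's genes of their per-gene
#' Z-scores; members absent from the matrix are skipped with a warning.
#' Because every nonconstant z row sums to zero across cells, the scores
#' over all scored cells also sum to zero.
#'
#' @param z z-matrix from [zscore_by_gene()].
#' @param set a [gene_set()].
#' @return a `cell_score_table`: data.frame with `cell`, `score`, and an
#'   empty `stratum` column to be filled by a stratification step.
#' @export
score_cells <- function(z, set) {
  if (!inherits(set, "gene_set"))
    pm_data_error("score_cells: `set` must be a gene_set")
  present <- intersect(set$members, rownames(z))
  if (length(present) == 0)
    pm_data_error(paste0(
      "score_cells: no member of '", set$name, "' present in the matrix; missing: ",
      paste(set$members, collapse = ", ")))
  missing <- setdiff(set$members, present)
  if (length(missing))
    warning(sprintf("score_cells: %d member(s) of '%s' absent and skipped: %s",
                    length(missing), set$name,
                    paste(utils::head(missing, 5), collapse = ", ")))
  score <- colSums(z[present, , drop = FALSE])
  out <- data.frame(cell = colnames(z), score = as.numeric(score),
                    stratum = NA_character_, stringsAsFactors = FALSE)
  class(out) <- c("cell_score_table", "data.frame")
  out
}

#' Stratify cells into score tertiles
#'
#' Cells are sorted by score descending (ties by identifier ascending);
#' the first `floor(n/3)` become the `high` stratum, the last `floor(n/3)`
#' the `low` stratum, and the remainder `mid`. The extreme strata are
#' always exactly `floor(n/3)` cells each, and the assignment depends only
#' on (score, identifier) pairs, never on input order.
#'
#' @param scores a `cell_score_table` from [score_cells()].
#' @return the table with `stratum` filled with `low`/`mid`/`high`.
#' @export
stratify_tertiles <- function(scores) {
  n <- nrow(scores)
  if (n < 3) pm_numeric_error("stratify_tertiles: need >= 3 cells")
  k <- n %/% 3L
  ord <- order(-scores$score, scores$cell)
  stratum <- rep("mid", n)
  stratum[ord[seq_len(k)]] <- "high"
  stratum[ord[(n - k + 1L):n]] <- "low"
  scores$stratum <- stratum
  scores
}

#' Stratify cells by a marker gene's own expression
#'
#' Trisects cells by the expression of one gene using lower-interpolation
#' empirical quantiles at `boundaries`: expression at or below the first
#' quantile is `neg`, above the second is `high`, in between `int`.
#' Zero-expression cells are always `neg`. Used to compare signature
#' scores across marker-defined strata (the CD62L-neg / -int / -high
#' comparison).
#'
#' @param sc an [expression_matrix()] (any scale).
#' @param gene symbol to stratify by.
#' @param boundaries two quantiles `q1 < q2` in (0, 1); default thirds.
#' @return a `cell_score_table` whose `score` column is the gene's
#'   expression and whose `stratum` is `neg`/`int`/`high`.
#' @export
stratify_by_gene <- function(sc, gene, boundaries = c(1 / 3, 2 / 3)) {
  if (!gene %in% rownames(sc))
    pm_data_error(paste0("stratify_by_gene: gene not in matrix: ", gene))
  if (length(boundaries) != 2 || boundaries[1] >= boundaries[2] ||
      boundaries[1] <= 0 || boundaries[2] >= 1)
    pm_config_error("stratify_by_gene: boundaries must satisfy 0 < q1 < q2 < 1")
  x <- as.numeric(sc[gene, ])
  qs <- stats::quantile(x, boundaries, type = 1, names = FALSE)
  stratum <- ifelse(x <= qs[1], "neg", ifelse(x > qs[2], "high", "int"))
  stratum[x == 0] <- "neg"
  if (all(x == 0))
    warning(paste0("stratify_by_gene: '", gene,
                   "' has zero expression in every cell; all cells are 'neg'"))
  out <- data.frame(cell = colnames(sc), score = x, stratum = stratum,
                    stringsAsFactors = FALSE)
  class(out) <- c("cell_score_table", "data.frame")
  out
}
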