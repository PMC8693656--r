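#' Expression matrix container
#'
#' A thin wrapper around a base numeric matrix (genes in rows, samples or
#' cells in columns) carrying two tags: the expression `scale`
#' (`"counts"` for raw counts, `"log2tpm"` for log2(TPM + 1)) and the
#' `role` of the columns (`"bulk"` replicates or `"single-cell"` cells).
#' Row names are gene symbols, column names are sample/cell identifiers;
#' both must be unique.
#'
#' @param mat numeric matrix with unique row (gene) and column names.
#' @param scale one of `"counts"`, `"log2tpm"`.
#' @param role one of `"bulk"`, `"single-cell"`.
#' @return the matrix with class `expr_matrix` and the two tag attributes.
#' @export
expression_matrix <- function(mat, scale = c("counts", "log2tpm"),
                              role = c("bulk", "single-cell")) {
  scale <- match.arg(scale)
  role <- match.arg(role)
  if (!is.matrix(mat) || !is.numeric(mat))
    pm_data_error("expression_matrix: `mat` must be a numeric matrix")
  if (is.null(rownames(mat)) || is.null(colnames(mat)))
    pm_data_error("expression_matrix: row (gene) and column names are required")
  if (anyDuplicated(rownames(mat)))
    pm_data_error("expression_matrix: duplicate gene symbols in rows")
  if (anyDuplicated(colnames(mat)))
    pm_data_error("expression_matrix: duplicate column identifiers")
  if (anyNA(mat))
    pm_data_error("expression_matrix: missing values are not permitted")
  structure(mat, class = c("expr_matrix", "matrix", "array"),
            scale = scale, role = role)
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d columns [%s, %s]\n",
              nrow(x), ncol(x), attr(x, "role"), attr(x, "scale")))
  invisible(x)
}

#' Expression scale tag of a matrix
#' @param x an `expr_matrix`.
#' @return `"counts"` or `"log2tpm"`.
#' @export
expr_scale <- function(x) attr(x, "scale")

#' Column role tag of a matrix
#' @param x an `expr_matrix`.
#' @return `"bulk"` or `"single-cell"`.
#' @export
expr_role <- function(x) attr(x, "role")

# subsetting keeps the tags
#' @export
`[.expr_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out))
    out <- structure(out, class = class(x),
                     scale = attr(x, "scale"), role = attr(x, "role"))
  out
}

#' Normalize raw counts to log2(TPM + 1)
#'
#' Each column is scaled to sum to one million and then transformed
#' elementwise by log2(x + 1). TPM here is column-proportional scaling
#' without gene-length correction (lengths are neither known nor simulated
#' for these matrices); the scale tag becomes `"log2tpm"`.
#'
#' @param expr an `expr_matrix` on the raw-count scale.
#' @return an `expr_matrix` of the same shape on the log2(TPM + 1) scale.
#' @export
normalize_to_log_tpm <- function(expr) {
  if (!inherits(expr, "expr_matrix"))
    pm_data_error("normalize_to_log_tpm: input must be an expr_matrix")
  if (expr_scale(expr) != "counts")
    pm_numeric_error(paste0(
      "normalize_to_log_tpm: input is already on scale '", expr_scale(expr),
      "'; refusing to double-normalize"))
  totals <- colSums(expr)
  if (any(totals <= 0)) {
    bad <- colnames(expr)[which(totals <= 0)]
    pm_numeric_error(paste0(
      "normalize_to_log_tpm: zero-total column(s): ",
      paste(bad, collapse = ", ")))
  }
  tpm <- sweep(unclass(expr), 2, totals, "/") * 1e6
  expression_matrix(log2(tpm + 1), scale = "log2tpm", role = expr_role(expr))
}
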