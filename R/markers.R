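#' Mann-Whitney rank-sum test
#'
#' Two-sided Mann-Whitney U with midranks for ties. When the combined
#' sample size is at most 12 and there are no ties, the p-value is exact
#' (two-sided: twice the smaller tail of the exact U null distribution,
#' capped at 1 — equivalent to counting rank assignments at least as
#' extreme). Otherwise the normal approximation is used with tie-corrected
#' variance and a 0.5 continuity correction. The reported U is for group
#' `a`: `U_a = R_a - |a|(|a|+1)/2`.
#'
#' @param a,b numeric vectors, each nonempty.
#' @return list with `u_statistic` and `p`.
#' @export
rank_sum_test <- function(a, b) {
  if (length(a) < 1 || length(b) < 1)
    pm_numeric_error("rank_sum_test: both groups must be nonempty")
  m <- length(a); n <- length(b); N <- m + n
  r <- rank(c(a, b))
  u <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  ties <- table(r)
  has_ties <- any(ties > 1)
  if (N <= 12 && !has_ties) {
    # exact null distribution of U (stats::pwilcox)
    lo <- stats::pwilcox(u, m, n)
    hi <- 1 - stats::pwilcox(u - 1, m, n)
    p <- min(1, 2 * min(lo, hi))
  } else {
    mu <- m * n / 2
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- m * n / 12 * (N + 1 - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
  }
  list(u_statistic = as.numeric(u), p = p)
}

#' Benjamini-Hochberg adjusted values
#'
#' Step-up FDR adjustment: with p-values sorted ascending,
#' `q_(i) = min_{j >= i} ( m * p_(j) / j )`, capped at 1 and mapped back
#' to the input order.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return vector of adjusted values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(is.na(p)) || any(p < 0 | p > 1))
    pm_numeric_error("bh_adjust: p-values must lie in [0, 1]")
  m <- length(p)
  ord <- order(p)
  q_sorted <- rev(cummin(rev(m * p[ord] / seq_len(m))))
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

#' Find genes upregulated in the score-low stratum
#'
#' For every gene, computes the mean log2(TPM + 1) difference between the
#' `low` and `high` strata (log2FC, low minus high) and a two-sided
#' rank-sum p-value across the cells of the two strata (mid-stratum cells
#' are excluded). BH adjustment runs over all tested genes. Genes passing
#' `log2fc >= log2(fc_threshold)` and `q <= q_threshold` are ranked — by
#' `(q ascending, log2fc descending, symbol)` when `order_by =
#' "significance"`, or by `(log2fc descending, q ascending, symbol)` when
#' `order_by = "log2fc"` — and the top `n_top` are returned. Genes with
#' zero expression in every cell of both strata have no defined test and
#' are skipped with a log line.
#'
#' @param sc an [expression_matrix()] on the log2(TPM + 1) scale.
#' @param strata a stratified `cell_score_table` with `low` and `high`
#'   strata (from [stratify_tertiles()]).
#' @param n_top number of top genes to report (default 10); `Inf` reports
#'   every passing gene.
#' @param fc_threshold minimum fold change, linear scale (default 2).
#' @param q_threshold FDR ceiling (default 0.05).
#' @param order_by `"significance"` (default) or `"log2fc"`.
#' @return a `marker_result` data.frame: `symbol`, `log2fc`,
#'   `u_statistic`, `p`, `q`, `is_surface` (NA until annotated), `rank`.
#'   The full per-gene table before thresholding is attached as attribute
#'   `tested` (the BH universe).
#' @export
find_markers <- function(sc, strata, n_top = 10, fc_threshold = 2,
                         q_threshold = 0.05,
                         order_by = c("significance", "log2fc")) {
  order_by <- match.arg(order_by)
  if (!inherits(sc, "expr_matrix") || expr_scale(sc) != "log2tpm")
    pm_data_error("find_markers: sc must be an expr_matrix on the log2(TPM+1) scale")
  if (n_top < 1) pm_config_error("find_markers: n_top must be >= 1")
  low_cells <- strata$cell[strata$stratum == "low"]
  high_cells <- strata$cell[strata$stratum == "high"]
  if (length(low_cells) == 0 || length(high_cells) == 0)
    pm_numeric_error("find_markers: empty low or high stratum")
  lo <- unclass(sc)[, low_cells, drop = FALSE]
  hi <- unclass(sc)[, high_cells, drop = FALSE]

  expressed <- rowSums(lo) + rowSums(hi) > 0
  if (any(!expressed))
    message(sprintf("find_markers: %d gene(s) with zero expression in both strata skipped",
                    sum(!expressed)))
  genes <- rownames(sc)[expressed]
  log2fc <- rowMeans(lo[expressed, , drop = FALSE]) -
    rowMeans(hi[expressed, , drop = FALSE])
  tests <- lapply(genes, function(g) rank_sum_test(lo[g, ], hi[g, ]))
  u <- vapply(tests, `[[`, 0, "u_statistic")
  p <- vapply(tests, `[[`, 0, "p")
  q <- bh_adjust(p)

  res <- data.frame(symbol = genes, log2fc = as.numeric(log2fc),
                    u_statistic = u, p = p, q = q,
                    is_surface = NA, rank = NA_integer_,
                    stringsAsFactors = FALSE)
  tested <- res
  pass <- res$log2fc >= log2(fc_threshold) & res$q <= q_threshold
  res <- res[pass, , drop = FALSE]
  ord <- if (order_by == "significance")
    order(res$q, -res$log2fc, res$symbol)
  else
    order(-res$log2fc, res$q, res$symbol)
  res <- res[ord, , drop = FALSE]
  if (is.finite(n_top)) res <- utils::head(res, n_top)
  res$rank <- seq_len(nrow(res))
  rownames(res) <- NULL
  class(res) <- c("marker_result", "data.frame")
  attr(res, "tested") <- tested
  res
}

#' Keep only surface-molecule-encoding candidates
#'
#' Subsets a marker table to genes flagged as surface molecules in the
#' annotation, preserving the incoming order and renumbering ranks.
#' Candidates missing from the annotation are treated as non-surface and
#' counted in a log line. An annotation containing no surface gene at all
#' is rejected as a misloaded file.
#'
#' @param results a `marker_result` from [find_markers()].
#' @param ann a [surface_annotation()].
#' @return the surface-only `marker_result` (possibly zero rows, with a
#'   warning).
#' @export
filter_surface <- function(results, ann) {
  if (!inherits(ann, "surface_annotation"))
    pm_data_error("filter_surface: `ann` must be a surface_annotation")
  if (!any(ann$is_surface))
    pm_data_error("filter_surface: annotation contains no surface gene (misloaded file?)")
  flag <- ann$is_surface[match(results$symbol, ann$symbol)]
  unannotated <- sum(is.na(flag))
  if (unannotated > 0)
    message(sprintf("filter_surface: %d candidate(s) absent from the annotation treated as non-surface",
                    unannotated))
  results$is_surface <- !is.na(flag) & flag
  out <- results[results$is_surface, , drop = FALSE]
  if (nrow(out) == 0)
    warning("filter_surface: no surface-molecule candidate at these thresholds")
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Map a gene set across species
#'
#' With an ortholog table, each symbol maps by exact match; one-to-many
#' mappings expand (flagged in a log line) and unmapped symbols drop with
#' a warning. Without a table, the standard symbol-case heuristic applies:
#' mouse to human upper-cases the symbol, human to mouse capitalizes the
#' first letter and lower-cases the rest. The result is de-duplicated,
#' order preserved.
#'
#' @param set a [gene_set()] whose species differs from `target_species`.
#' @param target_species target species tag.
#' @param table optional `ortholog_table` from [read_ortholog_table()].
#' @return a mapped [gene_set()] tagged with `target_species`.
#' @export
map_symbols <- function(set, target_species, table = NULL) {
  if (!inherits(set, "gene_set"))
    pm_data_error("map_symbols: `set` must be a gene_set")
  if (identical(set$species, target_species))
    pm_config_error("map_symbols: source and target species are identical")
  if (is.null(table)) {
    mapped <- switch(target_species,
      human = toupper(set$members),
      mouse = paste0(toupper(substr(set$members, 1, 1)),
                     tolower(substr(set$members, 2, nchar(set$members)))),
      pm_config_error(paste0(
        "map_symbols: no case heuristic for target species '", target_species,
        "'; supply an ortholog table")))
  } else {
    sub <- table[table$source_species == set$species &
                   table$target_species == target_species, , drop = FALSE]
    hits <- lapply(set$members, function(s)
      sub$target_symbol[sub$source_symbol == s])
    n_hits <- lengths(hits)
    if (any(n_hits == 0))
      warning(sprintf("map_symbols: %d unmapped symbol(s) dropped: %s",
                      sum(n_hits == 0),
                      paste(utils::head(set$members[n_hits == 0], 5),
                            collapse = ", ")))
    if (any(n_hits > 1))
      message(sprintf("map_symbols: %d symbol(s) with one-to-many mappings expanded",
                      sum(n_hits > 1)))
    mapped <- unlist(hits, use.names = FALSE)
  }
  mapped <- mapped[!duplicated(mapped)]
  if (length(mapped) == 0)
    pm_data_error(paste0("map_symbols: no symbol of '", set$name, "' could be mapped"))
  gene_set(set$name, mapped, species = target_species, k = set$k)
}
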