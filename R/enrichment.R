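#' Signal-to-noise ranked gene list
#'
#' Ranks every gene by the signal-to-noise ratio between two cell groups:
#' `(mu_a - mu_b) / (sd_a + sd_b)`, with each standard deviation floored
#' at `max(0.2 * |mu|, 0.2)` of its own group — the floor keeps
#' low-variance genes from producing unbounded ratios. Genes are sorted by
#' metric descending, ties broken lexicographically by symbol. If either
#' group has fewer than two members the metric falls back to the mean
#' difference (log2FC on the log scale) with a warning, since a standard
#' deviation needs two observations.
#'
#' @param expr an [expression_matrix()].
#' @param group_a,group_b disjoint vectors of column identifiers.
#' @return a `ranked_list` data.frame: `symbol`, `metric`, sorted
#'   descending.
#' @export
signal_to_noise <- function(expr, group_a, group_b) {
  if (length(intersect(group_a, group_b)) > 0)
    pm_config_error("signal_to_noise: groups overlap")
  miss <- setdiff(c(group_a, group_b), colnames(expr))
  if (length(miss))
    pm_data_error(paste0("signal_to_noise: unknown column(s): ",
                         paste(utils::head(miss, 5), collapse = ", ")))
  xa <- unclass(expr)[, group_a, drop = FALSE]
  xb <- unclass(expr)[, group_b, drop = FALSE]
  mu_a <- rowMeans(xa); mu_b <- rowMeans(xb)
  if (length(group_a) < 2 || length(group_b) < 2) {
    warning("signal_to_noise: a group has < 2 members; falling back to the mean-difference metric")
    metric <- mu_a - mu_b
  } else {
    sd_a <- apply(xa, 1, stats::sd)
    sd_b <- apply(xb, 1, stats::sd)
    sd_a <- pmax(sd_a, pmax(0.2 * abs(mu_a), 0.2))
    sd_b <- pmax(sd_b, pmax(0.2 * abs(mu_b), 0.2))
    metric <- (mu_a - mu_b) / (sd_a + sd_b)
  }
  ord <- order(-metric, rownames(expr))
  out <- data.frame(symbol = rownames(expr)[ord],
                    metric = as.numeric(metric[ord]),
                    stringsAsFactors = FALSE)
  class(out) <- c("ranked_list", "data.frame")
  out
}

#' Build a ranked list from symbols and metric values
#' @param symbols unique gene symbols.
#' @param metric finite metric values, same length.
#' @return a `ranked_list`, sorted metric descending, ties lexicographic.
#' @export
ranked_list <- function(symbols, metric) {
  if (anyDuplicated(symbols))
    pm_data_error("ranked_list: duplicate symbols")
  if (any(!is.finite(metric)))
    pm_numeric_error("ranked_list: metric must be finite")
  ord <- order(-metric, symbols)
  out <- data.frame(symbol = as.character(symbols)[ord],
                    metric = as.numeric(metric)[ord],
                    stringsAsFactors = FALSE)
  class(out) <- c("ranked_list", "data.frame")
  out
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Walks the ranked list: positions holding a set member increment the
#' running sum by `|metric|^weight_p / sum_hits |metric|^weight_p`, other
#' positions decrement by `1 / (N - N_hits)`. The enrichment score ES is
#' the running-sum value of maximal absolute deviation from zero, sign
#' preserved (first extremum on ties). With `weight_p = 0` this is the
#' classic KS statistic. If every hit metric is zero the hit weights
#' degenerate and equal weights are used. The leading edge holds the set
#' members at or before the extremum for positive ES, and at or after it
#' for negative ES.
#'
#' @param rl a `ranked_list`.
#' @param set a [gene_set()]; must hit at least one list gene and must not
#'   cover the entire list.
#' @param weight_p metric-weighting exponent (default 1).
#' @return list with `es`, `leading_edge`, `running_sum`.
#' @export
enrichment_score <- function(rl, set, weight_p = 1) {
  hit <- rl$symbol %in% set$members
  n <- nrow(rl); nh <- sum(hit)
  if (nh == 0)
    pm_data_error(paste0("enrichment_score: no member of '", set$name,
                         "' is in the ranked list"))
  if (nh == n)
    pm_data_error("enrichment_score: the set covers the entire ranked list")
  w <- abs(rl$metric)^weight_p
  denom <- sum(w[hit])
  inc <- if (denom > 0) w / denom else rep(1 / nh, n)
  step <- ifelse(hit, inc, -1 / (n - nh))
  running <- cumsum(step)
  i_max <- which.max(abs(running))
  es <- running[i_max]
  leading <- if (es >= 0) rl$symbol[seq_len(i_max)][hit[seq_len(i_max)]]
  else rl$symbol[i_max:n][hit[i_max:n]]
  list(es = es, leading_edge = leading, running_sum = running)
}

#' Gene-set enrichment analysis with a gene-label permutation null
#'
#' Computes the observed enrichment score of a set against the
#' signal-to-noise-ranked list between two groups, then draws `n_perm`
#' random same-size gene sets from the list (without replacement, seeded)
#' as the null. The permutation p-value is one-sided in the direction of
#' the observed ES, computed against the same-sign half of the null with
#' add-one smoothing in both numerator and denominator,
#' `p = (1 + #\{same-sign, |ES_null| >= |ES_obs|\}) / (1 + #\{same-sign\})`,
#' so it can never be zero and is uniform under a null set — the
#' convention of the reference GSEA implementation. NES divides the
#' observed ES by the mean
#' magnitude of same-sign null scores and is flagged undefined when no
#' null score shares the sign.
#'
#' Gene-label permutation (rather than phenotype permutation) is the
#' deliberate choice here: the group sizes this pipeline validates are as
#' small as three replicates, where phenotype permutation is degenerate.
#'
#' @param expr an [expression_matrix()].
#' @param group_a,group_b disjoint column-identifier vectors.
#' @param set a [gene_set()] with at least 2 members.
#' @param n_perm number of permutations, at least 100 (default 1000).
#' @param weight_p metric exponent (default 1).
#' @param seed RNG seed for the null draws.
#' @return an `enrichment_result` list: `set_name`, `es`, `nes`,
#'   `nes_defined`, `p_perm`, `n_perm`, `leading_edge`, `running_sum`,
#'   `seed`.
#' @export
gsea <- function(expr, group_a, group_b, set, n_perm = 1000, weight_p = 1,
                 seed = 1L) {
  rl <- signal_to_noise(expr, group_a, group_b)
  gsea_preranked(rl, set, n_perm = n_perm, weight_p = weight_p, seed = seed)
}

#' @rdname gsea
#' @param rl a precomputed `ranked_list`.
#' @export
gsea_preranked <- function(rl, set, n_perm = 1000, weight_p = 1, seed = 1L) {
  if (length(set$members) < 2)
    pm_config_error("gsea: set must have >= 2 members (degenerate null otherwise)")
  if (n_perm < 100)
    pm_config_error("gsea: n_perm must be >= 100")
  obs <- enrichment_score(rl, set, weight_p)
  size <- sum(rl$symbol %in% set$members)
  null_es <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    fake <- gene_set(".null", sample(rl$symbol, size), species = set$species)
    enrichment_score(rl, fake, weight_p)$es
  }, 0))
  same_sign <- sign(null_es) == sign(obs$es) | null_es == 0 & obs$es == 0
  p_perm <- (1 + sum(same_sign & abs(null_es) >= abs(obs$es))) /
    (1 + sum(same_sign))
  nes_defined <- any(same_sign & null_es != 0)
  nes <- if (nes_defined) obs$es / mean(abs(null_es[same_sign & null_es != 0]))
  else NA_real_
  structure(list(set_name = set$name, es = obs$es, nes = nes,
                 nes_defined = nes_defined, p_perm = p_perm,
                 n_perm = as.integer(n_perm),
                 leading_edge = obs$leading_edge,
                 running_sum = obs$running_sum, seed = as.integer(seed)),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("<enrichment_result> %s: ES=%.3f NES=%s p_perm=%.4g (n_perm=%d)\n",
              x$set_name, x$es,
              if (x$nes_defined) sprintf("%.3f", x$nes) else "undefined",
              x$p_perm, x$n_perm))
  invisible(x)
}

#' Summed-Z comparison of a gene set across strata
#'
#' Computes each cell's summed Z-score for the set, then summarizes it per
#' stratum (mean, sd, n) and tests the two extreme strata (`neg` vs
#' `high`, or `low` vs `high`) with the rank-sum test. This is the check
#' that marker-high cells carry the downstream program.
#'
#' @param sc an [expression_matrix()] on the log2(TPM + 1) scale.
#' @param set a [gene_set()].
#' @param strata a stratified `cell_score_table` (from
#'   [stratify_tertiles()] or [stratify_by_gene()]).
#' @return list with `summary` (data.frame `stratum`, `n`, `mean`, `sd`),
#'   `extremes` (the two strata tested), and `p`.
#' @export
zscore_set_comparison <- function(sc, set, strata) {
  scores <- score_cells(zscore_by_gene(sc), set)
  s <- strata$stratum[match(scores$cell, strata$cell)]
  if (anyNA(s))
    pm_data_error("zscore_set_comparison: strata do not cover every cell")
  levels_present <- unique(s)
  wanted <- if ("neg" %in% levels_present) c("neg", "int", "high")
  else c("low", "mid", "high")
  wanted <- intersect(wanted, levels_present)
  if (any(vapply(wanted, function(w) sum(s == w), 0L) == 0))
    pm_numeric_error("zscore_set_comparison: a stratum has zero cells")
  summary <- do.call(rbind, lapply(wanted, function(w) data.frame(
    stratum = w, n = sum(s == w),
    mean = mean(scores$score[s == w]),
    sd = stats::sd(scores$score[s == w]),
    stringsAsFactors = FALSE)))
  extremes <- wanted[c(1, length(wanted))]
  if (extremes[1] == extremes[2])
    pm_numeric_error("zscore_set_comparison: need at least two distinct strata")
  tst <- rank_sum_test(scores$score[s == extremes[2]],
                       scores$score[s == extremes[1]])
  list(summary = summary, extremes = extremes, p = tst$p)
}
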