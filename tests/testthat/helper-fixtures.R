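# Shared fixtures, all built in code.

# Default-parameter simulations are used by many tests; cache them per seed
# so the suite does not regenerate 2000x300 matrices repeatedly.
.sim_cache <- new.env(parent = emptyenv())
default_sim <- function(seed) {
  key <- as.character(seed)
  if (is.null(.sim_cache[[key]]))
    .sim_cache[[key]] <- simulate_dataset(sim_params(seed = seed))
  .sim_cache[[key]]
}

# A small log2(TPM+1)-tagged matrix from raw values (bypasses normalization
# for tests that exercise scale-independent arithmetic).
log_matrix <- function(vals, nr, nc, genes = NULL, cells = NULL,
                       role = "single-cell") {
  m <- matrix(vals, nr, nc)
  rownames(m) <- genes %||% sprintf("g%02d", seq_len(nr))
  colnames(m) <- cells %||% sprintf("c%02d", seq_len(nc))
  expression_matrix(m, scale = "log2tpm", role = role)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent enumeration oracle for the two-sided Mann-Whitney p-value:
# walks every C(m+n, m) assignment of ranks to group a, computes U, and
# takes twice the smaller tail (capped at 1).
enumerate_ranksum_p <- function(a, b) {
  m <- length(a); n <- length(b)
  r <- rank(c(a, b))
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  combos <- utils::combn(m + n, m)
  u_all <- apply(combos, 2, function(idx) sum(idx) - m * (m + 1) / 2)
  lo <- mean(u_all <= u_obs)
  hi <- mean(u_all >= u_obs)
  min(1, 2 * min(lo, hi))
}

# Independent step-by-step running-sum oracle for the enrichment score.
oracle_es <- function(symbols, metric, members, weight_p) {
  hit <- symbols %in% members
  n <- length(symbols); nh <- sum(hit)
  w <- abs(metric)^weight_p
  denom <- sum(w[hit])
  running <- numeric(n); acc <- 0
  for (i in seq_len(n)) {
    acc <- acc + if (hit[i]) {
      if (denom > 0) w[i] / denom else 1 / nh
    } else -1 / (n - nh)
    running[i] <- acc
  }
  running[which.max(abs(running))]
}
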