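test_that("signal-to-noise applies the stated standard-deviation floors", {
  # two tight groups: mu_a = 1, mu_b = 0, both sds under the floor
  vals <- c(rep(1, 3), rep(0, 3))
  m <- log_matrix(rep(vals, each = 1), 1, 6, genes = "g1")
  rl <- signal_to_noise(m, colnames(m)[1:3], colnames(m)[4:6])
  expect_equal(rl$metric, 1 / (0.2 + 0.2))  # = 2.5
  # identical groups: all metrics zero, order lexicographic
  set.seed(4)
  m2 <- log_matrix(rep(rnorm(5), 6), 5, 6, genes = c("e", "a", "c", "b", "d"))
  rl2 <- signal_to_noise(m2, colnames(m2)[1:3], colnames(m2)[4:6])
  expect_true(all(rl2$metric == 0))
  expect_identical(rl2$symbol, sort(rl2$symbol))
  expect_error(signal_to_noise(m2, colnames(m2)[1:3], colnames(m2)[3:5]),
               "overlap", class = "pm_config_error")
})

test_that("signal-to-noise matches a direct per-gene loop", {
  set.seed(19)
  m <- log_matrix(rnorm(1200, 5, 2), 100, 12)
  ga <- colnames(m)[1:6]; gb <- colnames(m)[7:12]
  rl <- signal_to_noise(m, ga, gb)
  oracle <- vapply(rownames(m), function(g) {
    xa <- as.numeric(m[g, ga]); xb <- as.numeric(m[g, gb])
    sa <- max(sd(xa), 0.2 * abs(mean(xa)), 0.2)
    sb <- max(sd(xb), 0.2 * abs(mean(xb)), 0.2)
    (mean(xa) - mean(xb)) / (sa + sb)
  }, 0)
  expect_equal(rl$metric[match(names(oracle), rl$symbol)],
               unname(oracle), tolerance = 1e-10)
  # a one-member group falls back to the mean-difference metric
  expect_warning(fb <- signal_to_noise(m, ga[1], gb), "< 2 members")
  expect_equal(fb$metric[match(rownames(m), fb$symbol)],
               unname(as.numeric(m[, ga[1]]) - rowMeans(unclass(m)[, gb])),
               tolerance = 1e-10)
})

test_that("enrichment score hits the closed-form boundary cases", {
  rl <- ranked_list(c("a", "b", "c", "d"), c(4, 3, 2, 1))
  top <- enrichment_score(rl, gene_set("top", c("a", "b")), weight_p = 0)
  expect_equal(top$running_sum, c(0.5, 1.0, 0.5, 0.0))
  expect_equal(top$es, 1.0)
  expect_identical(top$leading_edge, c("a", "b"))
  bottom <- enrichment_score(rl, gene_set("bot", c("c", "d")), weight_p = 0)
  expect_equal(bottom$es, -1.0)
  expect_identical(bottom$leading_edge, c("c", "d"))
  expect_error(enrichment_score(rl, gene_set("none", "zz")),
               class = "pm_data_error")
  expect_error(enrichment_score(rl, gene_set("all", c("a", "b", "c", "d"))),
               "entire", class = "pm_data_error")
})

test_that("enrichment score equals the independent running-sum oracle", {
  set.seed(23)
  for (i in 1:30) {
    n <- sample(20:100, 1)
    genes <- sprintf("G%03d", seq_len(n))
    metric <- rnorm(n)
    rl <- ranked_list(genes, metric)
    members <- sample(genes, sample(2:15, 1))
    for (p in c(0, 1)) {
      es <- enrichment_score(rl, gene_set("s", members), weight_p = p)$es
      expect_equal(es, oracle_es(rl$symbol, rl$metric, members, p),
                   tolerance = 1e-12)
    }
  }
})

test_that("ES is invariant to positive metric rescaling and negates on reversal", {
  set.seed(29)
  genes <- sprintf("G%02d", 1:40)
  metric <- rnorm(40)
  members <- sample(genes, 6)
  for (p in c(0, 0.5, 1, 2)) {
    e1 <- enrichment_score(ranked_list(genes, metric), gene_set("s", members), p)$es
    e2 <- enrichment_score(ranked_list(genes, metric * 37.5), gene_set("s", members), p)$es
    expect_equal(e1, e2, tolerance = 1e-12)
  }
  # reversal: flip the order (weight_p = 0 makes the walk symmetric)
  rl <- ranked_list(genes, metric)
  rev_rl <- rl[rev(seq_len(nrow(rl))), ]
  class(rev_rl) <- class(rl)
  e_f <- enrichment_score(rl, gene_set("s", members), 0)
  e_r <- oracle_es(rev_rl$symbol, rev_rl$metric, members, 0)
  expect_equal(e_f$es, -e_r, tolerance = 1e-12)
})

test_that("an extreme set is called significant and p is reproducible, never zero", {
  set.seed(31)
  genes <- sprintf("G%03d", 1:200)
  metric <- sort(rnorm(200), decreasing = TRUE)
  rl <- ranked_list(genes, metric)
  top_set <- gene_set("top10", rl$symbol[1:10])
  r1 <- gsea_preranked(rl, top_set, n_perm = 999, seed = 1)
  expect_lte(r1$p_perm, 0.01)
  expect_gt(r1$p_perm, 0)
  expect_gt(r1$es, 0)
  expect_true(r1$nes_defined && r1$nes > 1)
  r2 <- gsea_preranked(rl, top_set, n_perm = 999, seed = 1)
  expect_identical(r1$p_perm, r2$p_perm)
  expect_error(gsea_preranked(rl, gene_set("tiny", "G001"), n_perm = 200),
               ">= 2", class = "pm_config_error")
  expect_error(gsea_preranked(rl, top_set, n_perm = 50), "n_perm",
               class = "pm_config_error")
})

test_that("the downstream signature enriches in committed cells", {
  sim <- default_sim(7)
  sc <- normalize_to_log_tpm(sim$sc)
  bulk <- normalize_to_log_tpm(sim$bulk)
  committed <- colnames(sc)[colnames(sc) %in% sim$truth$committed_cell_ids]
  naive <- setdiff(colnames(sc), committed)
  gmp_sig <- derive_signature(bulk, "POP_B", "POP_A", k = 10)
  res <- gsea(sc, committed, naive, gmp_sig, n_perm = 500, seed = 11)
  expect_gt(res$es, 0)
  expect_lte(res$p_perm, 0.05)
  # the 200-gene validation set points the same way (most of its members
  # are bulk-noise picks, so only the direction is asserted)
  gmp_val <- derive_signature(bulk, "POP_B", "POP_A", k = 200)
  res200 <- gsea(sc, committed, naive, gmp_val, n_perm = 300, seed = 11)
  expect_gt(res200$es, 0)
})

test_that("summed-Z stratum comparison matches hand arithmetic and flags ties", {
  m <- log_matrix(c(1, 1, 1, 5, 5, 5), 1, 6, genes = "g1")
  strata <- data.frame(cell = colnames(m), score = NA,
                       stratum = rep(c("low", "high"), each = 3))
  cmp <- zscore_set_comparison(m, gene_set("s", "g1"), strata)
  z <- as.numeric(zscore_by_gene(m))
  expect_equal(cmp$summary$mean[cmp$summary$stratum == "low"], mean(z[1:3]))
  expect_equal(cmp$summary$mean[cmp$summary$stratum == "high"], mean(z[4:6]))
  expect_lt(cmp$p, 0.2)  # 3 vs 3 fully separated: exact p = 0.1
  # identical scores in every cell -> p = 1
  flat <- log_matrix(rep(2, 6), 1, 6, genes = "g1")
  expect_equal(zscore_set_comparison(flat, gene_set("s", "g1"), strata)$p, 1)
})

test_that("marker-defined strata separate the downstream program across seeds", {
  hits <- sum(vapply(1:20, function(s) {
    sim <- default_sim(s)
    sc <- normalize_to_log_tpm(sim$sc)
    strata <- stratify_by_gene(sc, sim$truth$planted_marker)
    cmp <- zscore_set_comparison(
      sc, gene_set("gmp", sim$truth$gmp_program_genes), strata)
    hi <- cmp$summary$mean[cmp$summary$stratum == "high"]
    lo <- cmp$summary$mean[cmp$summary$stratum == "neg"]
    hi > lo && cmp$p < 0.05
  }, TRUE))
  expect_gte(hits, 18)
})
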