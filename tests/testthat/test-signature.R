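test_that("derive_signature ranks by log-scale mean difference with stated tie-breaks", {
  m <- log_matrix(c(100, 1, 5, 100, 1, 5, 1, 100, 5, 1, 100, 5), 3, 4,
                  genes = c("geneX", "geneY", "geneZ"),
                  cells = c("POP_A_rep1", "POP_A_rep2", "POP_B_rep1", "POP_B_rep2"),
                  role = "bulk")
  sig <- derive_signature(m, "POP_A", "POP_B", k = 1)
  expect_identical(sig$members, "geneX")
  swapped <- derive_signature(m, "POP_B", "POP_A", k = 1)
  expect_identical(swapped$members, "geneY")
  # all-tie input: lexicographically-first eligible symbols, with a warning
  flat <- log_matrix(rep(3, 8), 4, 2, genes = c("d", "b", "a", "c"),
                     cells = c("POP_A_rep1", "POP_B_rep1"), role = "bulk")
  expect_warning(sig <- derive_signature(flat, "POP_A", "POP_B", k = 2),
                 "tied")
  expect_identical(sig$members, c("a", "b"))
  expect_error(derive_signature(m, "POP_C", "POP_B", k = 1),
               "unknown population label", class = "pm_config_error")
  expect_error(derive_signature(m, "POP_A", "POP_B", k = 99),
               "shortfall", class = "pm_config_error")
})

test_that("min_mean floor removes low-expression genes from eligibility", {
  m <- log_matrix(c(0.1, 9, 0.0, 5, 0.1, 9, 0.0, 5), 4, 2,
                  genes = c("lowA", "hiA", "lowB", "hiB"),
                  cells = c("POP_A_rep1", "POP_B_rep1"), role = "bulk")
  # lowA has the largest delta only among eligible if floor is off
  m["lowA", ] <- c(2, 0)
  m["hiA", ] <- c(9, 8)
  sig <- derive_signature(m, "POP_A", "POP_B", k = 1, min_mean = 3)
  expect_identical(sig$members, "hiA")
})

test_that("per-gene Z-scores match a brute-force loop and handle constants", {
  expect_equal(as.numeric(zscore_by_gene(log_matrix(c(1, 2, 3), 1, 3))),
               c(-1, 0, 1))
  expect_equal(as.numeric(zscore_by_gene(log_matrix(c(5, 5, 5), 1, 3))),
               c(0, 0, 0))
  set.seed(11)
  m <- log_matrix(rnorm(1000), 50, 20)
  z <- zscore_by_gene(m)
  oracle <- t(apply(unclass(m), 1, function(r) (r - mean(r)) / sd(r)))
  expect_true(max(abs(z - oracle)) < 1e-10)
  # nonconstant rows have mean 0 and sample sd 1
  expect_true(max(abs(rowMeans(z))) < 1e-9)
  expect_true(max(abs(apply(z, 1, sd) - 1)) < 1e-9)
  # idempotence: standardizing a standardized matrix changes nothing
  z2 <- zscore_by_gene(log_matrix(as.numeric(z), 50, 20))
  expect_true(max(abs(z2 - z)) < 1e-9)
  expect_error(zscore_by_gene(log_matrix(1, 1, 1)), "2 cells",
               class = "pm_numeric_error")
})

test_that("summed scores are exact sums of z rows and sum to zero", {
  set.seed(3)
  m <- log_matrix(rnorm(600), 30, 20)
  z <- zscore_by_gene(m)
  one <- score_cells(z, gene_set("one", "g05"))
  expect_equal(one$score, as.numeric(z["g05", ]))
  set_a <- gene_set("a", c("g01", "g02", "g03"))
  set_b <- gene_set("b", c("g10", "g11"))
  both <- gene_set("ab", c(set_a$members, set_b$members))
  expect_equal(score_cells(z, both)$score,
               score_cells(z, set_a)$score + score_cells(z, set_b)$score)
  expect_lt(abs(sum(score_cells(z, both)$score)), 1e-6 * ncol(m))
  expect_warning(score_cells(z, gene_set("x", c("g01", "nope"))), "absent")
  expect_error(score_cells(z, gene_set("y", c("nope1", "nope2"))),
               "nope1", class = "pm_data_error")
})

test_that("tertile stratification obeys the floor rule and identifier tie-break", {
  tbl <- data.frame(cell = paste0("c", 1:9), score = 1:9,
                    stratum = NA_character_)
  s <- stratify_tertiles(tbl)
  expect_setequal(s$cell[s$stratum == "high"], c("c7", "c8", "c9"))
  expect_setequal(s$cell[s$stratum == "low"], c("c1", "c2", "c3"))
  s10 <- stratify_tertiles(data.frame(cell = sprintf("c%02d", 1:10),
                                      score = rnorm(10), stratum = NA))
  expect_equal(sum(s10$stratum == "high"), 3)
  expect_equal(sum(s10$stratum == "low"), 3)
  expect_equal(sum(s10$stratum == "mid"), 4)
  # fully tied scores: deterministic identifier split
  tied <- data.frame(cell = c("a", "b", "c", "d", "e", "f"),
                     score = rep(1, 6), stratum = NA)
  st <- stratify_tertiles(tied)
  expect_setequal(st$cell[st$stratum == "high"], c("a", "b"))
  expect_setequal(st$cell[st$stratum == "low"], c("e", "f"))
  expect_error(stratify_tertiles(tied[1:2, ]), "3 cells",
               class = "pm_numeric_error")
})

test_that("tertile assignment is invariant to cell order", {
  set.seed(5)
  tbl <- data.frame(cell = sprintf("c%02d", 1:17),
                    score = sample(c(rnorm(10), rep(0.5, 7))), stratum = NA)
  ref <- stratify_tertiles(tbl)
  for (i in 1:5) {
    sh <- stratify_tertiles(tbl[sample(nrow(tbl)), ])
    expect_identical(sh$stratum[match(ref$cell, sh$cell)], ref$stratum)
  }
})

test_that("stratify_by_gene trisects with lower-interpolation quantiles", {
  m <- log_matrix(c(0, 0, 0, 1, 2, 5, 6, 9, 10), 1, 9, genes = "mk")
  s <- stratify_by_gene(m, "mk")
  x <- s$score
  expect_setequal(s$cell[s$stratum == "neg"], s$cell[x <= 0])
  expect_equal(sum(s$stratum == "neg"), 3)
  expect_setequal(s$cell[s$stratum == "high"], s$cell[x >= 6])
  zero <- log_matrix(rep(0, 4), 1, 4, genes = "mk")
  expect_warning(s0 <- stratify_by_gene(zero, "mk"), "zero expression")
  expect_true(all(s0$stratum == "neg"))
  expect_error(stratify_by_gene(m, "ghost"), "ghost", class = "pm_data_error")
})

test_that("planted structure orders signature scores as the model predicts", {
  sim <- default_sim(7)
  sc <- normalize_to_log_tpm(sim$sc)
  z <- zscore_by_gene(sc)
  committed <- colnames(sc) %in% sim$truth$committed_cell_ids
  gmp_scores <- score_cells(z, gene_set("gmp", sim$truth$gmp_program_genes))
  cmp_scores <- score_cells(z, gene_set("cmp", sim$truth$cmp_program_genes))
  expect_gt(mean(gmp_scores$score[committed]), mean(gmp_scores$score[!committed]))
  expect_gt(mean(cmp_scores$score[!committed]), mean(cmp_scores$score[committed]))
  # marker-defined strata order the downstream-program score the same way
  s <- stratify_by_gene(sc, sim$truth$planted_marker)
  gmp_by <- gmp_scores$score[match(s$cell, gmp_scores$cell)]
  expect_gt(mean(gmp_by[s$stratum == "high"]), mean(gmp_by[s$stratum == "neg"]))
})

test_that("the marker is higher in score-low than score-high cells across seeds", {
  hits <- sum(vapply(1:20, function(s) {
    sim <- default_sim(s)
    sc <- normalize_to_log_tpm(sim$sc)
    bulk <- normalize_to_log_tpm(sim$bulk)
    sig <- derive_signature(bulk, "POP_A", "POP_B", k = 10)
    strat <- stratify_tertiles(score_cells(zscore_by_gene(sc), sig))
    x <- as.numeric(sc[sim$truth$planted_marker, ])
    mean(x[strat$stratum == "low"]) > mean(x[strat$stratum == "high"])
  }, TRUE))
  expect_gte(hits, 18)
})
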