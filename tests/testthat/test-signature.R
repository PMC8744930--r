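test_that("Welch t-test handles symmetry, separation and degenerate input", {
  r <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$t_stat, 0)
  expect_equal(r$p_value, 1)
  sep <- welch_t(c(0, 0, 0, 0), c(10, 10, 10, 10))
  expect_lt(sep$p_value, 1e-10)
  expect_error(welch_t(1, c(1, 2)), class = "tregsig_validation_error")
  # agrees with the reference implementation on non-degenerate data
  set.seed(1)
  for (i in 1:20) {
    a <- rnorm(sample(3:15, 1)); b <- rnorm(sample(3:15, 1), mean = 0.5)
    ours <- welch_t(a, b)
    ref <- t.test(a, b)
    expect_equal(ours$t_stat, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("BH adjustment matches hand computation and is monotone", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))
  expect_equal(benjamini_hochberg(0.2), 0.2)
  expect_error(benjamini_hochberg(c(0.5, 1.2)),
               class = "tregsig_validation_error")
  # calls at q < alpha are non-decreasing in alpha
  set.seed(2)
  p <- runif(200)^2
  q <- benjamini_hochberg(p)
  alphas <- c(0.001, 0.01, 0.05, 0.1, 0.5)
  expect_true(all(diff(vapply(alphas, function(a) sum(q < a), numeric(1))) >= 0))
})

test_that("fold change is the linear ratio of log2 means", {
  expect_equal(fold_change(6, 5), 2)
  expect_equal(fold_change(5, 5), 1)
  expect_lt(fold_change(5.0, 4.37), 1.55)  # 2^0.63 = 1.548
  expect_equal(fold_change(5.0, 4.37), 2^0.63)
  expect_error(fold_change(Inf, 1), class = "tregsig_validation_error")
})

test_that("derive_signature validates its cell sets", {
  m <- random_matrix(10, 20, seed = 3)
  cells <- colnames(m$values)
  expect_error(derive_signature(m, cells[1:5], cells[4:10]),
               class = "tregsig_validation_error")
  expect_error(derive_signature(m, character(0), cells[1:5]),
               class = "tregsig_validation_error")
  expect_error(derive_signature(m, c("nope", cells[1]), cells[3:6]),
               class = "tregsig_validation_error")
})

test_that("derived signature is invariant to cell and gene ordering", {
  cfg <- sim_config(seed = 17, n_genes = 400, program_shift = 2,
                    n_cells = c(CD4_treg_lair2pos = 40, CD4_conv = 80,
                                CD8 = 60, other = 20))
  sim <- simulate_tils(cfg)
  pop <- sim$truth$population
  pos <- names(pop)[pop == "CD4_treg_lair2pos"]
  neg <- names(pop)[pop == "CD4_conv"]
  sig1 <- derive_signature(sim$matrix, pos, neg)
  perm_g <- sample(rownames(sim$matrix$values))
  perm_c <- sample(colnames(sim$matrix$values))
  m2 <- expression_matrix(sim$matrix$values[perm_g, perm_c])
  sig2 <- derive_signature(m2, sample(pos), sample(neg))
  expect_identical(sig1$genes, sig2$genes)
  expect_gt(length(sig1$genes), 0)
})

test_that("signature membership is monotone in both thresholds", {
  cfg <- sim_config(seed = 19, n_genes = 300, program_shift = 1.2,
                    n_cells = c(CD4_treg_lair2pos = 50, CD4_conv = 100,
                                CD8 = 60, other = 20))
  sim <- simulate_tils(cfg)
  pop <- sim$truth$population
  pos <- names(pop)[pop == "CD4_treg_lair2pos"]
  neg <- names(pop)[pop == "CD4_conv"]
  base <- derive_signature(sim$matrix, pos, neg, q_max = 0.001, fc_min = 1.55)
  looser_q <- derive_signature(sim$matrix, pos, neg, q_max = 0.01, fc_min = 1.55)
  looser_fc <- derive_signature(sim$matrix, pos, neg, q_max = 0.001, fc_min = 1.2)
  expect_true(all(base$genes %in% looser_q$genes))
  expect_true(all(base$genes %in% looser_fc$genes))
})

test_that("correlation screen ranks constructed co-expressed genes on top", {
  set.seed(4)
  n <- 60
  anchor <- rnorm(n, 5, 2)
  planted <- t(replicate(20, anchor + rnorm(n, sd = 0.5)))
  noise <- matrix(rnorm(980 * n, 5, 2), 980, n)
  vals <- rbind(planted, noise)
  rownames(vals) <- c(sprintf("coexp%02d", 1:20), sprintf("rand%03d", 1:980))
  vals <- rbind(ANCHOR = anchor, NEG = -anchor + 10, vals)
  colnames(vals) <- sprintf("s%02d", 1:n)
  m <- expression_matrix(pmax(vals, 0))
  res <- correlation_screen(m, "ANCHOR", top_k = 500, r_min = 0.37)
  expect_false("ANCHOR" %in% res$gene_id)
  expect_false("NEG" %in% res$gene_id)     # r = -1 fails r_min
  expect_true(all(grepl("^coexp", res$gene_id[1:20])))
  expect_true(all(res$r > 0.37))
  # identical gene has r exactly 1
  v2 <- rbind(ANCHOR = anchor, TWIN = anchor)
  colnames(v2) <- sprintf("s%02d", 1:n)
  res2 <- correlation_screen(expression_matrix(pmax(v2, 0)), "ANCHOR")
  expect_equal(res2$r[res2$gene_id == "TWIN"], 1)
  # zero-variance anchor is an error
  v3 <- rbind(ANCHOR = rep(1, 5), g = rnorm(5, 3))
  colnames(v3) <- paste0("s", 1:5)
  expect_error(correlation_screen(expression_matrix(pmax(v3, 0)), "ANCHOR"),
               class = "tregsig_validation_error")
})
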