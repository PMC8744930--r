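test_that("noise-free limit puts program genes exactly at base_mean + shift", {
  cfg <- sim_config(seed = 3, base_sd = 0, dropout_rate0 = -Inf,
                    n_genes = 300, program_shift = 2.5,
                    n_cells = c(CD4_treg_lair2pos = 20, CD4_conv = 30,
                                CD8 = 30, other = 10))
  sim <- simulate_tils(cfg)
  treg <- names(sim$truth$population)[sim$truth$population == "CD4_treg_lair2pos"]
  vals <- sim$matrix$values[cfg$program_genes, treg]
  expect_true(all(vals == cfg$base_mean + 2.5))
  conv <- names(sim$truth$population)[sim$truth$population == "CD4_conv"]
  expect_true(all(sim$matrix$values[cfg$program_genes, conv] == cfg$base_mean))
  expect_true(all(sim$matrix$values["CD4", conv] ==
                    cfg$base_mean + cfg$marker_shift))
})

test_that("simulation is deterministic in the seed", {
  cfg <- sim_config(seed = 11, n_genes = 200,
                    program_genes = c("LAIR2", "FOXP3", "IL2RA", "CTLA4",
                                      "TNFRSF18", "ICOS", "TIGIT", "CCR8"),
                    n_cells = c(CD4_treg_lair2pos = 15, CD4_conv = 30,
                                CD8 = 30, other = 10),
                    n_samples = 40)
  a <- simulate_tils(cfg); b <- simulate_tils(cfg)
  expect_identical(a$matrix$values, b$matrix$values)
  sig <- cfg$program_genes
  ba <- simulate_bulk_cohort(cfg, sig); bb <- simulate_bulk_cohort(cfg, sig)
  expect_identical(as.data.frame(ba$clinical), as.data.frame(bb$clinical))
  expect_identical(ba$matrix$values, bb$matrix$values)
})

test_that("CD4+LAIR2+ gate recovers the designed Treg fraction", {
  cfg <- sim_config(seed = 5)
  sim <- simulate_tils(cfg)
  n <- ncol(sim$matrix$values)
  design_frac <- sum(sim$truth$population == "CD4_treg_lair2pos") / n
  gated <- apply_gate(sim$matrix, list(gate("CD4"), gate("LAIR2")))
  gate_frac <- length(gated) / n
  se <- sqrt(design_frac * (1 - design_frac) / n)
  expect_lt(abs(gate_frac - design_frac), 3 * se)
  # and the gated set is dominated by true Treg cells
  expect_gt(mean(sim$truth$population[gated] == "CD4_treg_lair2pos"), 0.9)
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(program_genes = c("LAIR2", "FOXP3")),
               class = "tregsig_config_error")  # markers missing
  expect_error(sim_config(program_shift = -1), class = "tregsig_config_error")
  expect_error(sim_config(planted_beta = Inf), class = "tregsig_config_error")
  expect_error(sim_config(n_genes = 5), class = "tregsig_config_error")
  cfg <- sim_config(n_genes = 300)
  expect_error(simulate_bulk_cohort(cfg, c("NOT_A_GENE")),
               class = "tregsig_config_error")
})

test_that("censoring behaves as configured", {
  cfg0 <- sim_config(seed = 9, n_genes = 250, n_samples = 80, censor_rate = 0)
  bulk0 <- simulate_bulk_cohort(cfg0, cfg0$program_genes[1:10])
  expect_true(all(bulk0$clinical$event == 1))

  # empirical event fraction decreases monotonically in censor_rate
  rates <- c(0, 0.01, 0.05, 0.2)
  fracs <- vapply(rates, function(r) {
    cfg <- sim_config(seed = 21, n_genes = 250, n_samples = 400,
                      censor_rate = r)
    mean(simulate_bulk_cohort(cfg, cfg$program_genes[1:10])$clinical$event)
  }, numeric(1))
  expect_true(all(diff(fracs) < 0))
})

test_that("bulk cohorts carry a recoverable planted score", {
  cfg <- sim_config(seed = 13, n_samples = 150)
  sig <- cfg$program_genes
  bulk <- simulate_bulk_cohort(cfg, sig)
  scores <- signature_score(bulk$matrix, sig)
  expect_gt(cor(scores, bulk$truth$score[names(scores)]), 0.98)
})
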