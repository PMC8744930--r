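test_that("Kaplan-Meier matches the hand product-limit fixture", {
  km <- kaplan_meier(c(2, 4, 5), c(1, 1, 0))
  expect_equal(km_surv_at(km, 2), 2 / 3)
  expect_equal(km_surv_at(km, 4), 1 / 3)
  expect_equal(km_surv_at(km, 5), 1 / 3)
  expect_equal(km_surv_at(km, 1), 1)

  allc <- kaplan_meier(c(3, 6, 9), c(0, 0, 0))
  expect_true(all(allc$surv == 1))
  expect_error(kaplan_meier(numeric(0), numeric(0)),
               class = "tregsig_validation_error")
})

test_that("KM with no censoring equals one minus the ECDF", {
  set.seed(8)
  t <- round(rexp(40, 0.1), 2)
  km <- kaplan_meier(t, rep(1, 40))
  ref <- km_oracle(t, rep(1, 40))
  expect_equal(km$surv[match(ref$time, km$time)], ref$surv, tolerance = 1e-12)
  for (tt in ref$time)
    expect_equal(km_surv_at(km, tt), mean(t > tt), tolerance = 1e-12)
})

test_that("log-rank test is symmetric and null on identical groups", {
  t <- c(2, 3, 5, 7, 2, 3, 5, 7); e <- c(1, 1, 0, 1, 1, 1, 0, 1)
  g <- rep(0:1, each = 4)
  r <- logrank_test(t, e, g)
  expect_equal(r$chi_square, 0, tolerance = 1e-12)
  expect_equal(r$p_value, 1, tolerance = 1e-12)

  set.seed(9)
  t2 <- rexp(30, 0.1); e2 <- rbinom(30, 1, 0.8); g2 <- rep(0:1, 15)
  expect_equal(logrank_test(t2, e2, g2), logrank_test(t2, e2, 1 - g2))
  expect_error(logrank_test(t2, e2, rep(1, 30)),
               class = "tregsig_validation_error")
  # package statistic agrees with the definition-based helper
  expect_equal(logrank_test(t2, e2, g2)$chi_square,
               logrank_chisq_oracle(t2, e2, g2), tolerance = 1e-8)
})

test_that("Cox fit is invariant to time scaling and covariate shifts", {
  set.seed(10)
  n <- 60
  x <- rnorm(n)
  t <- rexp(n, 0.05 * exp(0.6 * x))
  e <- rbinom(n, 1, 0.85)
  d <- data.frame(os_time = t, event = e, x = x)
  f0 <- cox_fit(d, "x")
  d2 <- d; d2$os_time <- d$os_time * 12
  expect_equal(cox_fit(d2, "x")$coefficients$coef, f0$coefficients$coef,
               tolerance = 1e-8)
  d3 <- d; d3$x <- d$x + 100
  expect_equal(cox_fit(d3, "x")$coefficients$coef, f0$coefficients$coef,
               tolerance = 1e-6)
  xb <- as.numeric(x > 0)
  db <- data.frame(os_time = t, event = e, x = xb)
  dn <- data.frame(os_time = t, event = e, x = 1 - xb)
  expect_equal(cox_fit(dn, "x")$coefficients$coef,
               -cox_fit(db, "x")$coefficients$coef, tolerance = 1e-6)
})

test_that("Efron and Breslow agree without ties; errors are classed", {
  set.seed(11)
  d <- data.frame(os_time = sample(seq(1, 400), 50), event = rbinom(50, 1, 0.8),
                  x = rnorm(50))
  fe <- cox_fit(d, "x", ties = "efron")
  fb <- cox_fit(d, "x", ties = "breslow")
  expect_equal(fe$coefficients$coef, fb$coefficients$coef, tolerance = 1e-10)

  expect_error(cox_fit(data.frame(os_time = 1:4, event = rep(0, 4), x = rnorm(4)),
                       "x"), class = "tregsig_validation_error")
  expect_error(cox_fit(data.frame(os_time = 1:4, event = rep(1, 4),
                                  x = rep(2, 4)), "x"),
               class = "tregsig_validation_error")
  # monotone likelihood (perfect separation) is refused, not reported
  sep <- data.frame(os_time = 1:8, event = rep(1, 8),
                    x = c(1, 1, 1, 1, 0, 0, 0, 0))
  expect_error(cox_fit(sep, "x"), class = "tregsig_separation_error")
})

test_that("identical groups give a null hazard ratio, with log-rank attached", {
  t <- c(2, 3, 5, 7, 9, 2, 3, 5, 7, 9); e <- c(1, 1, 0, 1, 1, 1, 1, 0, 1, 1)
  d <- data.frame(os_time = t, event = e, g = rep(0:1, each = 5))
  fit <- cox_fit(d, "g")
  expect_equal(fit$coefficients$coef, 0, tolerance = 1e-8)
  expect_equal(fit$coefficients$hr, 1, tolerance = 1e-8)
  expect_equal(fit$logrank_p, 1, tolerance = 1e-8)
})

test_that("missing covariates are dropped complete-case with a count", {
  set.seed(12)
  n <- 50
  d <- data.frame(os_time = rexp(n, 0.05), event = rbinom(n, 1, 0.9),
                  x = rnorm(n))
  d$x[1:7] <- NA
  fit <- cox_fit(d, "x")
  expect_equal(fit$n_missing_dropped, 7L)
  expect_equal(fit$n, n - 7L)
})

test_that("a horizon beyond all follow-up changes nothing", {
  set.seed(13)
  d <- data.frame(os_time = rexp(40, 0.05), event = rbinom(40, 1, 0.8),
                  x = rnorm(40))
  expect_equal(cox_fit(d, "x", horizon_months = 1e6)$coefficients,
               cox_fit(d, "x")$coefficients, tolerance = 1e-12)
  # a binding horizon censors events beyond it
  f60 <- cox_fit(d, "x", horizon_months = 20)
  expect_lte(f60$n_events, sum(d$event))
})

test_that("log-rank and univariate Cox Wald tests agree in rejection", {
  set.seed(14)
  agree <- 0
  n_rep <- 200
  for (i in seq_len(n_rep)) {
    n <- 200
    g <- rep(0:1, each = n / 2)
    t <- rexp(n, 0.03 * exp(0.5 * g))
    cens <- rexp(n, 0.015)
    d <- data.frame(os_time = pmin(t, cens), event = as.numeric(t <= cens),
                    g = g)
    wald_p <- cox_fit(d, "g")$coefficients$p
    lr_p <- logrank_test(d$os_time, d$event, g)$p_value
    agree <- agree + ((wald_p < 0.05) == (lr_p < 0.05))
  }
  expect_gte(agree / n_rep, 0.95)
})

test_that("the prognostic screen ranks a planted gene first", {
  set.seed(15)
  hits <- 0
  n_seeds <- 10
  for (s in seq_len(n_seeds)) {
    n <- 400
    genes <- sprintf("g%02d", 1:30)
    vals <- matrix(rnorm(30 * n, 8, 1), 30, n,
                   dimnames = list(genes, sprintf("p%03d", 1:n)))
    risk <- vals["g01", ] - 8     # the planted prognostic gene
    t <- rexp(n, 0.02 * exp(log(2) * risk))
    cens <- rexp(n, 0.01)
    clin <- clinical_table(data.frame(
      sample_id = colnames(vals), os_time = pmin(t, cens),
      event = as.numeric(t <= cens), stringsAsFactors = FALSE))
    m <- expression_matrix(vals, scale = "log2_intensity")
    tab <- gene_screen(m, genes, clin, dichotomize = "continuous")
    hits <- hits + (tab$gene_id[1] == "g01")
  }
  expect_gte(hits / n_seeds, 0.9)
})

test_that("constant genes are skipped by the screen, not fatal", {
  set.seed(16)
  n <- 60
  vals <- rbind(flat = rep(5, n), ok = rnorm(n, 8))
  colnames(vals) <- sprintf("p%02d", 1:n)
  clin <- clinical_table(data.frame(
    sample_id = colnames(vals), os_time = rexp(n, 0.05),
    event = rbinom(n, 1, 0.8), stringsAsFactors = FALSE))
  tab <- gene_screen(expression_matrix(vals, scale = "log2_intensity"),
                     c("flat", "ok", "absent"), clin,
                     dichotomize = "continuous")
  expect_equal(tab$gene_id, "ok")
  expect_match(attr(tab, "skipped")[["flat"]], "constant")
  expect_error(gene_screen(expression_matrix(vals, scale = "log2_intensity"),
                           "absent", clin),
               class = "tregsig_validation_error")
})
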