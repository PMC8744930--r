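# Independent brute-force oracles. These re-derive each quantity from its
# definition and are kept free of the package's implementation paths.

# Benjamini-Hochberg by the literal step-up definition:
# q_(i) = min_{j >= i} p_(j) * m / j, capped at 1, in input order.
bh_stepup_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q_sorted <- pmin(q_sorted, 1)
  out <- numeric(m)
  out[o] <- q_sorted
  out
}

# Efron log partial likelihood, written out from the definition.
# Single covariate x; reduces to Breslow when no event times are tied.
efron_loglik <- function(beta, time, event, x, breslow = FALSE) {
  eta <- beta * x
  r <- exp(eta)
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    D <- which(time == t & event == 1)
    R <- which(time >= t)
    d <- length(D)
    sR <- sum(r[R])
    sD <- sum(r[D])
    ll <- ll + sum(eta[D])
    l <- seq_len(d) - 1
    ll <- ll - if (breslow) d * log(sR) else sum(log(sR - (l / d) * sD))
  }
  ll
}

# Grid-search maximizer of the partial likelihood at 1e-4 resolution.
cox_grid_oracle <- function(time, event, x, lo = -3, hi = 3, by = 1e-4,
                            breslow = FALSE) {
  grid <- seq(lo, hi, by = by)
  ll <- vapply(grid, efron_loglik, numeric(1),
               time = time, event = event, x = x, breslow = breslow)
  grid[which.max(ll)]
}

# Two-group log-rank chi-square from the definition (hypergeometric
# moments at each event time); used for permutation nulls.
logrank_chisq_oracle <- function(time, event, group) {
  g <- as.logical(group)
  O <- 0; E <- 0; V <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & g)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# Kaplan-Meier by the hand product-limit formula.
km_oracle <- function(time, event) {
  s <- 1
  out <- numeric(0)
  for (t in sort(unique(time))) {
    n <- sum(time >= t)
    d <- sum(time == t & event == 1)
    s <- s * (1 - d / n)
    out <- c(out, s)
  }
  data.frame(time = sort(unique(time)), surv = out)
}
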