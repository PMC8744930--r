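#' Pool log hazard ratios across cohorts
#'
#' Inverse-variance meta-analysis of per-study log hazard ratios.
#' Fixed effect: weights `1/SE^2`, pooled estimate the weighted mean,
#' pooled `SE = 1/sqrt(sum(w))`. Random effects use the
#' DerSimonian-Laird moment estimator
#' `tau^2 = max(0, (Q - df) / C)` with `C = sum(w) - sum(w^2)/sum(w)`,
#' then weights `1/(SE^2 + tau^2)`. Heterogeneity is summarized by
#' Cochran's Q, `tau^2` and `I^2 = max(0, (Q - df)/Q) * 100`.
#' Confidence intervals are normal-theory on the log scale and
#' exponentiated.
#'
#' @param log_hr per-study log hazard ratios.
#' @param se per-study standard errors (> 0).
#' @param method `"fixed"` or `"dersimonian_laird"`.
#' @param labels optional study labels.
#' @return A `meta_result`: `studies` (data.frame with log_hr, se,
#'   weight), and pooled `log_hr`, `se`, `hr`, `ci_low`, `ci_high`,
#'   `method`, plus `Q`, `df`, `tau2`, `I2`.
#' @examples
#' pool_hr(c(0.3, 0.5), c(0.1, 0.2))  # pooled log HR 0.34, SE 0.08944
#' @export
pool_hr <- function(log_hr, se, method = c("fixed", "dersimonian_laird"),
                    labels = NULL) {
  method <- match.arg(method)
  if (!length(log_hr) || length(log_hr) != length(se))
    abort("log_hr and se must be non-empty and of equal length",
          "tregsig_validation_error")
  if (any(!is.finite(log_hr)) || any(!is.finite(se)) || any(se <= 0))
    abort("all SE must be finite and > 0", "tregsig_validation_error")
  if (is.null(labels)) labels <- paste0("study", seq_along(log_hr))
  k <- length(log_hr)
  w_fixed <- 1 / se^2
  mu_fixed <- sum(w_fixed * log_hr) / sum(w_fixed)
  Q <- sum(w_fixed * (log_hr - mu_fixed)^2)
  df <- k - 1
  tau2 <- if (k > 1) {
    C <- sum(w_fixed) - sum(w_fixed^2) / sum(w_fixed)
    max(0, (Q - df) / C)
  } else 0
  I2 <- if (Q > 0 && df > 0) max(0, (Q - df) / Q) * 100 else 0
  w <- if (method == "fixed") w_fixed else 1 / (se^2 + tau2)
  mu <- sum(w * log_hr) / sum(w)
  se_pooled <- 1 / sqrt(sum(w))
  z <- qnorm(0.975)
  structure(list(
    studies = data.frame(label = labels, log_hr = log_hr, se = se,
                         weight = w, stringsAsFactors = FALSE),
    log_hr = mu, se = se_pooled, hr = exp(mu),
    ci_low = exp(mu - z * se_pooled), ci_high = exp(mu + z * se_pooled),
    method = method, Q = Q, df = df, tau2 = tau2, I2 = I2),
    class = "meta_result")
}

#' Pool hazard ratios from fitted Cox models
#'
#' Convenience wrapper extracting one term's log HR and SE from each of a
#' list of [cox_fit()] results and pooling them with [pool_hr()].
#'
#' @param fits list of `survival_fit` objects.
#' @param term covariate name to pool (default: first term of each fit).
#' @inheritParams pool_hr
#' @return A `meta_result`.
#' @export
pool_cox_fits <- function(fits, term = NULL,
                          method = c("fixed", "dersimonian_laird"),
                          labels = NULL) {
  est <- vapply(fits, function(f) {
    tab <- f$coefficients
    row <- if (is.null(term)) tab[1L, ] else tab[tab$term == term, ]
    if (!nrow(row)) abort(sprintf("term not found: %s", term),
                          "tregsig_validation_error")
    c(row$coef, row$se)
  }, numeric(2))
  pool_hr(est[1, ], est[2, ], method = method, labels = labels)
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("<meta_result> %d studies, %s\n", nrow(x$studies), x$method))
  print(x$studies, digits = 4)
  cat(sprintf("pooled HR = %.3f (95%% CI %.3f-%.3f), log HR = %.4f (SE %.4f)\n",
              x$hr, x$ci_low, x$ci_high, x$log_hr, x$se))
  cat(sprintf("heterogeneity: Q = %.3f (df %d), tau2 = %.4f, I2 = %.1f%%\n",
              x$Q, x$df, x$tau2, x$I2))
  invisible(x)
}
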