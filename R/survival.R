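#' Administrative censoring at a horizon
#'
#' Truncates follow-up at `horizon` months: subjects with longer follow-up
#' are censored at the horizon. This is the standard way to turn overall
#' survival into a fixed-horizon (e.g. 5-year) endpoint before fitting.
#'
#' @param times follow-up times (months).
#' @param events event indicators (0/1).
#' @param horizon horizon in months; `NULL` means no truncation.
#' @return list with `times`, `events`.
#' @export
admin_censor <- function(times, events, horizon = NULL) {
  if (is.null(horizon)) return(list(times = times, events = events))
  if (!is.finite(horizon) || horizon <= 0)
    abort("horizon must be a positive number of months", "tregsig_validation_error")
  events <- ifelse(times > horizon, 0, events)
  list(times = pmin(times, horizon), events = events)
}

#' Kaplan-Meier product-limit estimator
#'
#' Wraps [survival::survfit()] for a single group; ties at a time are
#' handled deaths-before-censorings, the product-limit convention.
#'
#' @param times non-negative follow-up times (months).
#' @param events 0 = censored, 1 = death.
#' @return A `km_curve` data.frame: `time`, `n_risk`, `n_event`,
#'   `n_censor`, `surv` (survival probability just after `time`).
#' @export
kaplan_meier <- function(times, events) {
  if (!length(times)) abort("empty input", "tregsig_validation_error")
  if (length(times) != length(events))
    abort("times and events differ in length", "tregsig_validation_error")
  if (any(times < 0)) abort("negative time", "tregsig_validation_error")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, n_censor = fit$n.censor,
                    surv = fit$surv)
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Survival probability at a time, from a KM curve
#'
#' @param km a `km_curve`.
#' @param t time (months).
#' @return S(t), the step-function value at `t`.
#' @export
km_surv_at <- function(km, t) {
  idx <- km$time <= t
  if (!any(idx)) return(1)
  km$surv[max(which(idx))]
}

#' Two-group log-rank test
#'
#' Wraps [survival::survdiff()]; p-value from chi-square with 1 df.
#'
#' @param times,events as in [kaplan_meier()].
#' @param group binary group labels (two non-empty levels).
#' @return list with `chi_square`, `p_value`.
#' @export
logrank_test <- function(times, events, group) {
  g <- as.factor(group)
  if (nlevels(droplevels(g)) != 2L)
    abort("log-rank test needs exactly 2 non-empty groups",
          "tregsig_validation_error")
  sd <- survival::survdiff(survival::Surv(times, events) ~ g)
  list(chi_square = sd$chisq, p_value = pchisq(sd$chisq, 1, lower.tail = FALSE))
}

#' Cox proportional hazards fit
#'
#' Fits a Cox model by partial-likelihood maximization
#' ([survival::coxph()]) with the Efron tie correction by default
#' (Breslow available). Hazard ratios are reported with normal-theory
#' 95% confidence intervals on the log scale and Wald p-values. Rows with
#' a missing covariate are dropped (complete-case) and counted. When the
#' model has a single binary covariate, the log-rank p-value is attached.
#'
#' @param data a data.frame (e.g. a `clinical_table`, possibly merged with
#'   scores/groups) containing `os_time`, `event` and the covariates.
#' @param covariates character vector of covariate column names.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @param horizon_months optional administrative-censoring horizon applied
#'   before fitting (e.g. 60 for a 5-year endpoint).
#' @return A `survival_fit`: list with `coefficients` (data.frame: term,
#'   coef, se, hr, ci_low, ci_high, p), `n`, `n_events`, `loglik`
#'   (log partial likelihood at the optimum), `ties`, `logrank_p`,
#'   `n_missing_dropped`, `horizon_months`.
#' @export
cox_fit <- function(data, covariates, ties = c("efron", "breslow"),
                    horizon_months = NULL) {
  ties <- match.arg(ties)
  miss <- setdiff(c("os_time", "event", covariates), names(data))
  if (length(miss))
    abort(paste("missing column(s):", paste(miss, collapse = ", ")),
          "tregsig_validation_error")
  df <- as.data.frame(data)[, c("os_time", "event", covariates), drop = FALSE]
  cc <- complete.cases(df)
  n_dropped <- sum(!cc)
  df <- df[cc, , drop = FALSE]
  ac <- admin_censor(df$os_time, df$event, horizon_months)
  df$os_time <- ac$times; df$event <- ac$events
  if (sum(df$event) < 1)
    abort("no events after censoring: cannot fit", "tregsig_validation_error")
  for (cv in covariates) {
    v <- df[[cv]]
    if (is.numeric(v) && length(unique(v)) == 1L)
      abort(sprintf("covariate is constant: %s", cv), "tregsig_validation_error")
  }
  fml <- stats::as.formula(paste(
    "survival::Surv(os_time, event) ~",
    paste(sprintf("`%s`", covariates), collapse = " + ")))
  fit <- withCallingHandlers(
    survival::coxph(fml, data = df, ties = ties),
    warning = function(w) {
      if (grepl("infinite|converged before", conditionMessage(w)))
        abort(paste("monotone likelihood / possible separation:",
                    conditionMessage(w)), "tregsig_separation_error")
      invokeRestart("muffleWarning")
    })
  coefs <- summary(fit)$coefficients
  tab <- data.frame(
    term = rownames(coefs),
    coef = coefs[, "coef"],
    se = coefs[, "se(coef)"],
    hr = exp(coefs[, "coef"]),
    ci_low = exp(coefs[, "coef"] - qnorm(0.975) * coefs[, "se(coef)"]),
    ci_high = exp(coefs[, "coef"] + qnorm(0.975) * coefs[, "se(coef)"]),
    p = coefs[, "Pr(>|z|)"],
    stringsAsFactors = FALSE, row.names = NULL)
  logrank_p <- NA_real_
  if (length(covariates) == 1L) {
    v <- df[[covariates]]
    if (length(unique(v)) == 2L)
      logrank_p <- logrank_test(df$os_time, df$event, v)$p_value
  }
  structure(list(coefficients = tab, n = nrow(df), n_events = sum(df$event),
                 loglik = fit$loglik[2L], ties = ties, logrank_p = logrank_p,
                 n_missing_dropped = n_dropped,
                 horizon_months = if (is.null(horizon_months)) NA_real_
                                  else horizon_months),
            class = "survival_fit")
}

#' @export
print.survival_fit <- function(x, ...) {
  cat(sprintf("<survival_fit> n = %d, events = %d, ties = %s\n",
              x$n, x$n_events, x$ties))
  tab <- x$coefficients
  tab$hr_ci <- sprintf("%.2f (%.2f-%.2f)", tab$hr, tab$ci_low, tab$ci_high)
  print(tab[, c("term", "coef", "se", "hr_ci", "p")], digits = 3)
  if (!is.na(x$logrank_p)) cat(sprintf("log-rank p = %.4g\n", x$logrank_p))
  invisible(x)
}

#' Per-gene prognostic Cox screen
#'
#' Fits a univariate Cox model for each gene at a fixed survival horizon
#' (default 60 months, i.e. 5-year overall survival). The per-gene
#' predictor is either expression dichotomized at the cohort median
#' (`dichotomize = "median"`, high vs low) or continuous expression.
#' Results are sorted by Wald p-value with a Benjamini-Hochberg q column.
#' Genes with constant expression (or a constant dichotomized predictor)
#' are skipped and listed in the `skipped` attribute with a reason.
#'
#' @param x an `expr_matrix` (samples must match `clinical$sample_id`).
#' @param gene_list genes to screen (intersected with the matrix).
#' @param clinical a `clinical_table`.
#' @param horizon_months administrative-censoring horizon (default 60).
#' @param dichotomize `"median"` or `"continuous"`.
#' @return data.frame: `gene_id`, `coef`, `se`, `hr`, `ci_low`, `ci_high`,
#'   `p`, `q`, `n`, `n_events`; attribute `skipped`.
#' @export
gene_screen <- function(x, gene_list, clinical, horizon_months = 60,
                        dichotomize = c("median", "continuous")) {
  stopifnot(inherits(x, "expr_matrix"))
  dichotomize <- match.arg(dichotomize)
  genes <- intersect(gene_list, rownames(x$values))
  if (!length(genes))
    abort("no gene from gene_list present in the matrix",
          "tregsig_validation_error")
  common <- intersect(clinical$sample_id, colnames(x$values))
  if (length(common) < 2L)
    abort("clinical table and matrix share < 2 samples",
          "tregsig_validation_error")
  cl <- as.data.frame(clinical)[match(common, clinical$sample_id), ]
  rows <- list(); skipped <- list()
  for (g in genes) {
    v <- x$values[g, common]
    pred <- if (dichotomize == "median") as.numeric(v > median(v)) else v
    if (length(unique(pred)) < 2L) {
      skipped[[g]] <- "constant predictor"
      next
    }
    dat <- data.frame(os_time = cl$os_time, event = cl$event, expr = pred)
    fit <- tryCatch(
      cox_fit(dat, "expr", horizon_months = horizon_months),
      tregsig_error = function(e) NULL)
    if (is.null(fit)) {
      skipped[[g]] <- "fit failed (separation or no events)"
      next
    }
    co <- fit$coefficients
    rows[[g]] <- data.frame(gene_id = g, coef = co$coef, se = co$se,
                            hr = co$hr, ci_low = co$ci_low,
                            ci_high = co$ci_high, p = co$p,
                            n = fit$n, n_events = fit$n_events,
                            stringsAsFactors = FALSE)
  }
  if (!length(rows))
    abort("every screened gene was skipped", "tregsig_validation_error")
  out <- do.call(rbind, rows)
  out <- out[order(out$p, out$gene_id), , drop = FALSE]
  out$q <- benjamini_hochberg(out$p)
  rownames(out) <- NULL
  attr(out, "skipped") <- unlist(skipped)
  out
}
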