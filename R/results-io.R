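#' Write a pipeline result to TSV or JSON
#'
#' Supported objects: `survival_fit`, `meta_result`,
#' `risk_stratification`, `signature_gene_set`, `quadrant_stats`,
#' `km_curve` and plain data.frames (screen tables). JSON output keeps
#' full numeric precision, so [read_results()] round-trips every numeric
#' field; TSV output is a flat human-readable table (for a `meta_result`,
#' one row per study plus a pooled row).
#'
#' @param object a supported result object.
#' @param path output file.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_results <- function(object, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  type <- result_type(object)
  if (format == "json") {
    payload <- c(list(type = type), result_payload(object, type))
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  } else {
    tab <- result_table(object, type)
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

result_type <- function(object) {
  for (cl in c("survival_fit", "meta_result", "risk_stratification",
               "signature_gene_set", "quadrant_stats", "km_curve"))
    if (inherits(object, cl)) return(cl)
  if (is.data.frame(object)) return("table")
  abort(sprintf("cannot serialize object of class %s",
                paste(class(object), collapse = "/")),
        "tregsig_validation_error")
}

result_payload <- function(object, type) {
  switch(type,
    survival_fit = list(coefficients = object$coefficients, n = object$n,
                        n_events = object$n_events, loglik = object$loglik,
                        ties = object$ties, logrank_p = object$logrank_p,
                        n_missing_dropped = object$n_missing_dropped,
                        horizon_months = object$horizon_months),
    meta_result = list(studies = object$studies, log_hr = object$log_hr,
                       se = object$se, hr = object$hr,
                       ci_low = object$ci_low, ci_high = object$ci_high,
                       method = object$method, Q = object$Q, df = object$df,
                       tau2 = object$tau2, I2 = object$I2),
    risk_stratification = list(samples = as.data.frame(object),
                               cutoff = attr(object, "cutoff")),
    signature_gene_set = list(genes = object$genes, q_max = object$q_max,
                              fc_min = object$fc_min, table = object$table),
    quadrant_stats = list(gene_x = object$gene_x, gene_y = object$gene_y,
                          threshold = object$threshold,
                          counts = as.list(object$counts),
                          percent = as.list(object$percent),
                          boundary = object$boundary, total = object$total),
    km_curve = list(curve = as.data.frame(object)),
    table = list(table = as.data.frame(object)))
}

result_table <- function(object, type) {
  switch(type,
    survival_fit = cbind(object$coefficients, n = object$n,
                         n_events = object$n_events),
    meta_result = {
      st <- object$studies
      st$hr <- exp(st$log_hr)
      st$ci_low <- exp(st$log_hr - qnorm(0.975) * st$se)
      st$ci_high <- exp(st$log_hr + qnorm(0.975) * st$se)
      pooled <- data.frame(label = "pooled", log_hr = object$log_hr,
                           se = object$se, weight = NA_real_,
                           hr = object$hr, ci_low = object$ci_low,
                           ci_high = object$ci_high,
                           stringsAsFactors = FALSE)
      rbind(st, pooled)
    },
    risk_stratification = as.data.frame(object),
    signature_gene_set = {
      if (is.null(object$table)) {
        data.frame(gene_id = object$genes, stringsAsFactors = FALSE)
      } else {
        tab <- object$table
        tab[match(object$genes, tab$gene_id), , drop = FALSE]
      }
    },
    quadrant_stats = data.frame(
      quadrant = c(names(object$counts), "boundary"),
      count = c(unname(object$counts), object$boundary),
      percent = c(unname(object$percent),
                  100 * object$boundary / object$total)),
    km_curve = as.data.frame(object),
    table = as.data.frame(object))
}

#' Read back a JSON result written by [write_results()]
#'
#' Reconstructs the original object class from the stored `type` field.
#'
#' @param path JSON file written by `write_results(..., format = "json")`.
#' @return The reconstructed result object.
#' @export
read_results <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  type <- x$type
  switch(type,
    survival_fit = structure(
      list(coefficients = as.data.frame(x$coefficients), n = x$n,
           n_events = x$n_events, loglik = x$loglik, ties = x$ties,
           logrank_p = if (is.null(x$logrank_p)) NA_real_ else x$logrank_p,
           n_missing_dropped = x$n_missing_dropped,
           horizon_months = if (is.null(x$horizon_months)) NA_real_
                            else x$horizon_months),
      class = "survival_fit"),
    meta_result = structure(
      list(studies = as.data.frame(x$studies), log_hr = x$log_hr, se = x$se,
           hr = x$hr, ci_low = x$ci_low, ci_high = x$ci_high,
           method = x$method, Q = x$Q, df = x$df, tau2 = x$tau2, I2 = x$I2),
      class = "meta_result"),
    risk_stratification = {
      out <- as.data.frame(x$samples)
      out$group <- factor(out$group, levels = c("low", "high"))
      attr(out, "cutoff") <- x$cutoff
      class(out) <- c("risk_stratification", "data.frame")
      out
    },
    signature_gene_set = structure(
      list(genes = unlist(x$genes),
           table = if (is.null(x$table)) NULL else as.data.frame(x$table),
           q_max = x$q_max, fc_min = x$fc_min,
           n_pos = NA_integer_, n_neg = NA_integer_),
      class = "signature_gene_set"),
    quadrant_stats = structure(
      list(gene_x = x$gene_x, gene_y = x$gene_y, threshold = x$threshold,
           counts = unlist(x$counts), percent = unlist(x$percent),
           boundary = x$boundary, total = x$total),
      class = "quadrant_stats"),
    km_curve = {
      out <- as.data.frame(x$curve)
      class(out) <- c("km_curve", "data.frame")
      out
    },
    table = as.data.frame(x$table),
    abort(sprintf("unknown result type in file: %s", type),
          "tregsig_format_error"))
}
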