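#' Read a clinical table
#'
#' Reads a delimited table of per-sample overall-survival data and
#' covariates. Required columns: `sample_id`, `os_time` (months),
#' `event` (0 = censored, 1 = death). Recognized optional covariates:
#' `age` (years), `sex` (female/male), `smoking` (no/yes), `stage`
#' (I/II/other), `histology` (micropapillary, solid, acinar, papillary,
#' lepidic, or other).
#'
#' Categorical covariates are additionally encoded as the standard
#' clinico-pathologic contrasts used for lung adenocarcinoma multivariable
#' models: stage II vs I (`stage_ii`), female vs male (`sex_female`),
#' never- vs ever-smoker (`smoking_no`), micropapillary/solid vs
#' acinar/papillary/lepidic pattern (`hist_mp_solid`). Categories outside
#' a contrast (e.g. stage IV) are kept in the table but coded `NA` in the
#' contrast column, so they drop out of that model by complete-case
#' handling rather than silently.
#'
#' @param path delimited text file (tab separated by default).
#' @param sep field separator.
#' @return A `clinical_table` (a `data.frame`).
#' @export
read_clinical_table <- function(path, sep = "\t") {
  df <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  clinical_table(df)
}

#' Construct/validate a clinical table
#'
#' @param df a data.frame with at least `sample_id`, `os_time`, `event`.
#' @return A validated, contrast-encoded `clinical_table`.
#' @export
clinical_table <- function(df) {
  need <- c("sample_id", "os_time", "event")
  miss <- setdiff(need, names(df))
  if (length(miss))
    abort(paste("missing required clinical column(s):",
                paste(miss, collapse = ", ")), "tregsig_validation_error")
  df$sample_id <- as.character(df$sample_id)
  check_unique(df$sample_id, "sample")
  df$os_time <- as.numeric(df$os_time)
  df$event <- as.numeric(df$event)
  if (anyNA(df$os_time) || any(!is.finite(df$os_time)) || any(df$os_time < 0))
    abort("os_time must be finite and >= 0", "tregsig_validation_error")
  if (!all(df$event %in% c(0, 1)))
    abort("event must be 0 (censored) or 1 (death)", "tregsig_validation_error")
  df <- encode_covariates(df)
  class(df) <- c("clinical_table", "data.frame")
  df
}

encode_covariates <- function(df) {
  code <- function(x, one, zero) {
    x <- tolower(trimws(as.character(x)))
    out <- rep(NA_real_, length(x))
    out[x %in% one] <- 1
    out[x %in% zero] <- 0
    out
  }
  if ("stage" %in% names(df))
    df$stage_ii <- code(df$stage, "ii", "i")
  if ("sex" %in% names(df))
    df$sex_female <- code(df$sex, c("female", "f"), c("male", "m"))
  if ("smoking" %in% names(df))
    df$smoking_no <- code(df$smoking, c("no", "never"), c("yes", "ever"))
  if ("histology" %in% names(df))
    df$hist_mp_solid <- code(df$histology,
                             c("micropapillary", "solid", "micropapillary/solid"),
                             c("acinar", "papillary", "lepidic",
                               "acinar/papillary/lepidic"))
  if ("age" %in% names(df)) df$age <- as.numeric(df$age)
  df
}

#' Write a clinical table to TSV
#'
#' @param x a `clinical_table`.
#' @param path output file.
#' @export
write_clinical_table <- function(x, path) {
  stopifnot(inherits(x, "clinical_table"))
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
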