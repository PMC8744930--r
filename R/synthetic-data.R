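#' Simulation configuration
#'
#' Bundles and validates every parameter of the synthetic single-cell and
#' bulk-cohort generators. Defaults emulate a sorted-TIL single-cell
#' experiment in which a CD4+ regulatory T-cell population carries a
#' co-expressed LAIR2/FOXP3 program, and bulk tumor cohorts whose hazard
#' of death is log-linear in a planted signature score.
#'
#' One global integer `seed` is expanded into independent per-stage
#' substreams, so the single-cell and bulk stages can be rerun
#' independently and reproducibly.
#'
#' @param seed integer master seed.
#' @param n_cells named counts per population: `CD4_treg_lair2pos`
#'   (the LAIR2+ Treg population), `CD4_conv` (conventional CD4),
#'   `CD8`, `other`.
#' @param n_genes total gene universe size (markers included).
#' @param program_genes genes co-elevated in the Treg population; must
#'   include `FOXP3`, `LAIR2` and the tumor-Treg markers `IL2RA`,
#'   `CTLA4`, `TNFRSF18`, `ICOS`, `TIGIT`, `CCR8`. The default is a
#'   231-gene program (markers plus numbered `TRG` genes), matching the
#'   scale of the Treg signature such an experiment yields; with a large
#'   program the cohort-level mean score is an essentially noiseless
#'   readout of the latent score, as it is for real multi-hundred-gene
#'   signatures.
#' @param program_shift log2 units added to program genes in Treg cells.
#' @param marker_shift log2 units added to `CD4` in CD4 populations and
#'   to `CD8A` in the CD8 population.
#' @param base_mean,base_sd background expression mean/sd, log2(TPM+1).
#' @param dropout_rate0,dropout_slope logistic zero-inflation: a value is
#'   zeroed with probability `plogis(dropout_rate0 - dropout_slope * mu)`
#'   where `mu` is its population mean, so lowly expressed genes drop out
#'   more.
#' @param n_samples bulk cohort size.
#' @param bulk_base_mean,bulk_base_sd bulk log2 expression background.
#' @param score_coupling log2 expression units added to each signature
#'   gene per unit of the latent score.
#' @param planted_beta log hazard per unit of the latent score.
#' @param baseline_hazard events per month at score 0.
#' @param censor_rate independent exponential censoring rate (events per
#'   month); 0 disables censoring.
#' @param covariate_effects named log-hazard effects for `age` (per year,
#'   centered at 65), `sex_female`, `stage_ii`.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_cells = c(CD4_treg_lair2pos = 200, CD4_conv = 600,
                                   CD8 = 800, other = 150),
                       n_genes = 1500,
                       program_genes = c("LAIR2", "FOXP3", "IL2RA", "CTLA4",
                                         "TNFRSF18", "ICOS", "TIGIT", "CCR8",
                                         sprintf("TRG%03d", seq_len(223))),
                       program_shift = 5,
                       marker_shift = 5,
                       base_mean = 1.5, base_sd = 1,
                       dropout_rate0 = 1.5, dropout_slope = 0.8,
                       n_samples = 300,
                       bulk_base_mean = 8, bulk_base_sd = 1,
                       score_coupling = 1,
                       planted_beta = log(2),
                       baseline_hazard = 0.015,
                       censor_rate = 0.01,
                       covariate_effects = c(age = 0, sex_female = 0,
                                             stage_ii = 0)) {
  pops <- c("CD4_treg_lair2pos", "CD4_conv", "CD8", "other")
  if (!all(pops %in% names(n_cells)) || any(n_cells[pops] <= 0))
    abort("n_cells needs positive counts for all four populations",
          "tregsig_config_error")
  required <- c("FOXP3", "LAIR2", "IL2RA", "CTLA4", "TNFRSF18", "ICOS",
                "TIGIT", "CCR8")
  miss <- setdiff(required, program_genes)
  if (length(miss))
    abort(paste("program_genes must include:", paste(miss, collapse = ", ")),
          "tregsig_config_error")
  if (program_shift < 0)
    abort("program_shift must be >= 0", "tregsig_config_error")
  if (!is.finite(planted_beta))
    abort("planted_beta must be finite", "tregsig_config_error")
  if (n_samples < 2 || n_genes < length(program_genes) + 2)
    abort("gene universe too small for the program genes plus CD4/CD8A",
          "tregsig_config_error")
  if (baseline_hazard <= 0 || censor_rate < 0)
    abort("baseline_hazard must be > 0 and censor_rate >= 0",
          "tregsig_config_error")
  structure(list(seed = as.integer(seed), n_cells = n_cells[pops],
                 n_genes = n_genes, program_genes = program_genes,
                 program_shift = program_shift, marker_shift = marker_shift,
                 base_mean = base_mean, base_sd = base_sd,
                 dropout_rate0 = dropout_rate0, dropout_slope = dropout_slope,
                 n_samples = n_samples, bulk_base_mean = bulk_base_mean,
                 bulk_base_sd = bulk_base_sd, score_coupling = score_coupling,
                 planted_beta = planted_beta,
                 baseline_hazard = baseline_hazard, censor_rate = censor_rate,
                 covariate_effects = covariate_effects),
            class = "sim_config")
}

# deterministic per-stage substream seed, kept within 32-bit range
substream <- function(seed, stage) {
  as.integer((as.numeric(seed) %% 1000003) * 2017 + stage * 7919) %%
    2147483647L
}

# shared gene universe: markers + program genes + numbered filler
sim_gene_universe <- function(config) {
  special <- unique(c("CD4", "CD8A", config$program_genes))
  n_fill <- config$n_genes - length(special)
  if (n_fill < 0)
    abort("n_genes smaller than the marker/program gene set",
          "tregsig_config_error")
  c(special, sprintf("G%05d", seq_len(n_fill)))
}

#' Simulate a sorted-TIL single-cell expression matrix
#'
#' Draws per-cell, per-gene expression as
#' `max(0, Normal(mu, base_sd))` on the log2(TPM+1) scale, where `mu` is
#' `base_mean` plus the population shifts (`CD4` up in both CD4
#' populations, `CD8A` up in the CD8 population, program genes up only in
#' the Treg population), then zeroes each value with the logistic dropout
#' probability of its `mu`. The `other` population carries no elevation,
#' standing in for non-T or unassigned cells.
#'
#' @param config a [sim_config()].
#' @return list with `matrix` (an `expr_matrix`, genes x cells),
#'   `annotation` (cell_id, population, patient, tissue) and `truth`
#'   (population labels and planted program genes).
#' @export
simulate_tils <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(substream(config$seed, 1L))
  genes <- sim_gene_universe(config)
  pops <- rep(names(config$n_cells), config$n_cells)
  n_cells <- length(pops)
  cells <- sprintf("cell%05d", seq_len(n_cells))

  mu <- matrix(config$base_mean, length(genes), n_cells,
               dimnames = list(genes, cells))
  cd4_cols <- pops %in% c("CD4_treg_lair2pos", "CD4_conv")
  mu["CD4", cd4_cols] <- mu["CD4", cd4_cols] + config$marker_shift
  mu["CD8A", pops == "CD8"] <- mu["CD8A", pops == "CD8"] + config$marker_shift
  treg_cols <- pops == "CD4_treg_lair2pos"
  mu[config$program_genes, treg_cols] <-
    mu[config$program_genes, treg_cols] + config$program_shift

  vals <- pmax(mu + rnorm(length(mu), sd = config$base_sd), 0)
  p_drop <- plogis(config$dropout_rate0 - config$dropout_slope * mu)
  vals[runif(length(vals)) < p_drop] <- 0

  ann <- data.frame(
    cell_id = cells, population = pops,
    patient = paste0("P", (seq_len(n_cells) %% 14L) + 1L),
    tissue = "tumor", stringsAsFactors = FALSE)
  list(
    matrix = expression_matrix(vals, scale = "log2_tpm_plus1"),
    annotation = ann,
    truth = list(population = setNames(pops, cells),
                 program_genes = config$program_genes,
                 program_shift = config$program_shift))
}

#' Simulate a bulk tumor cohort with survival tied to a signature score
#'
#' Each sample carries a latent score `s ~ Normal(0, 1)`; signature genes
#' gain `score_coupling * s` log2 units over a Normal background, so the
#' per-sample signature score is recoverable from expression. Survival
#' times are exponential with hazard
#' `baseline_hazard * exp(planted_beta * s + covariate effects)`, censored
#' by an independent exponential at `censor_rate`; the recorded follow-up
#' is the minimum, with the death indicator.
#'
#' @param config a [sim_config()].
#' @param signature a `signature_gene_set` or character vector of genes;
#'   all must exist in the simulated gene universe.
#' @return list with `matrix` (`expr_matrix`, scale `log2_intensity`),
#'   `clinical` (a `clinical_table`) and `truth` (per-sample `score`,
#'   `planted_beta`, `signature_genes`).
#' @export
simulate_bulk_cohort <- function(config, signature) {
  stopifnot(inherits(config, "sim_config"))
  genes <- sim_gene_universe(config)
  sig <- if (inherits(signature, "signature_gene_set")) signature$genes
         else as.character(signature)
  bad <- setdiff(sig, genes)
  if (length(bad))
    abort(sprintf("signature gene(s) absent from the simulated universe: %s",
                  paste(head(bad, 5L), collapse = ", ")),
          "tregsig_config_error")
  set.seed(substream(config$seed, 2L))
  n <- config$n_samples
  ids <- sprintf("sample%04d", seq_len(n))

  s <- rnorm(n)
  vals <- matrix(rnorm(length(genes) * n, mean = config$bulk_base_mean,
                       sd = config$bulk_base_sd),
                 length(genes), n, dimnames = list(genes, ids))
  vals[sig, ] <- vals[sig, ] +
    matrix(config$score_coupling * s, length(sig), n, byrow = TRUE)

  age <- round(rnorm(n, 65, 10))
  sex <- sample(c("female", "male"), n, replace = TRUE)
  smoking <- sample(c("no", "yes"), n, replace = TRUE, prob = c(0.3, 0.7))
  stage <- sample(c("I", "II", "III"), n, replace = TRUE,
                  prob = c(0.5, 0.3, 0.2))
  histology <- sample(c("micropapillary", "solid", "acinar", "papillary",
                        "lepidic"), n, replace = TRUE)
  eff <- config$covariate_effects
  lp <- config$planted_beta * s +
    eff[["age"]] * (age - 65) +
    eff[["sex_female"]] * (sex == "female") +
    eff[["stage_ii"]] * (stage == "II")
  death_t <- rexp(n, rate = config$baseline_hazard * exp(lp))
  cens_t <- if (config$censor_rate > 0) rexp(n, rate = config$censor_rate)
            else rep(Inf, n)
  clin <- clinical_table(data.frame(
    sample_id = ids, os_time = pmin(death_t, cens_t),
    event = as.numeric(death_t <= cens_t),
    age = age, sex = sex, smoking = smoking, stage = stage,
    histology = histology, stringsAsFactors = FALSE))
  list(
    matrix = expression_matrix(vals, scale = "log2_intensity"),
    clinical = clin,
    truth = list(score = setNames(s, ids),
                 planted_beta = config$planted_beta,
                 signature_genes = sig))
}
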