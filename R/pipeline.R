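#' End-to-end synthetic validation pipeline
#'
#' Runs the whole analysis on synthetic data with planted ground truth:
#'
#' 1. simulate a sorted-TIL single-cell matrix;
#' 2. gate CD4+LAIR2+ vs CD4+LAIR2- cells at the log2(TPM+1) > 4 cut-off;
#' 3. derive the Treg signature by per-gene Welch testing
#'    (BH q < 0.001, fold change >= 1.55, up-regulated only);
#' 4. simulate `n_cohorts` independent bulk cohorts whose hazard is
#'    log-linear in a latent score coupled to the signature genes;
#' 5. score each cohort, median-split into risk groups, fit Cox models on
#'    the continuous score and on the high-vs-low group;
#' 6. pool the per-cohort continuous-score log hazard ratios into an
#'    overall HR.
#'
#' @param seed master seed; cohort seeds are derived substreams.
#' @param config a [sim_config()] for the single-cell stage; cohort
#'   configs reuse it with per-cohort seeds.
#' @param n_cohorts number of bulk validation cohorts.
#' @param meta_method pooling method, see [pool_hr()].
#' @return list with `tils`, `gates` (`pos_cells`, `neg_cells`),
#'   `quadrants`, `signature`, `cohorts` (each with scores,
#'   stratification, score/group Cox fits), `meta_score`, `meta_group`.
#' @export
run_pipeline <- function(seed = 1L, config = sim_config(seed = seed),
                         n_cohorts = 3L,
                         meta_method = c("fixed", "dersimonian_laird")) {
  meta_method <- match.arg(meta_method)
  tils <- simulate_tils(config)
  pos <- apply_gate(tils$matrix, list(gate("CD4"), gate("LAIR2")))
  neg <- apply_gate(tils$matrix, list(gate("CD4"),
                                      gate("LAIR2", direction = "negative")))
  quad <- quadrant_fractions(tils$matrix, "CD4", "LAIR2")
  sig <- derive_signature(tils$matrix, pos, neg)
  if (!length(sig$genes))
    abort("derived signature is empty; cannot score cohorts",
          "tregsig_validation_error")

  cohorts <- lapply(seq_len(n_cohorts), function(i) {
    cfg <- config
    cfg$seed <- substream(config$seed, 100L + i)
    bulk <- simulate_bulk_cohort(cfg, sig)
    scores <- signature_score(bulk$matrix, sig)
    strat <- median_split(scores)
    dat <- as.data.frame(bulk$clinical)
    dat$score <- as.numeric(scores[dat$sample_id])
    dat$risk_high <- as.numeric(
      strat$group[match(dat$sample_id, strat$sample_id)] == "high")
    list(bulk = bulk, scores = scores, stratification = strat,
         fit_score = cox_fit(dat, "score"),
         fit_group = cox_fit(dat, "risk_high"))
  })
  list(
    tils = tils, gates = list(pos_cells = pos, neg_cells = neg),
    quadrants = quad, signature = sig, cohorts = cohorts,
    meta_score = pool_cox_fits(lapply(cohorts, `[[`, "fit_score"),
                               method = meta_method),
    meta_group = pool_cox_fits(lapply(cohorts, `[[`, "fit_group"),
                               method = meta_method))
}
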