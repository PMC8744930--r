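# tregsig

Derivation and prognostic validation of a tumor-infiltrating CD4+ LAIR2+
regulatory T-cell (Treg) gene signature.

## What it does

Tumor-infiltrating Tregs suppress anti-tumor immunity, and signatures of
their abundance are prognostic in lung adenocarcinoma. `tregsig`
implements the full analysis chain as tested R functions:

* **Gating** — flow-style thresholding of single-cell log2(TPM+1)
  expression (`gate()`, `apply_gate()`), with quadrant co-expression
  statistics (`quadrant_fractions()`) using strict `> t` / `< t`
  inequalities and an explicit boundary count.
* **Signature derivation** — per-gene Welch t-tests between gated
  CD4+LAIR2+ and CD4+LAIR2− cells, Benjamini–Hochberg FDR, and retention
  of up-regulated genes with `q < 0.001` and fold change
  `FC = 2^(Δ mean log2) ≥ 1.55` (`derive_signature()`); plus a Pearson
  co-expression screen against an anchor gene (`correlation_screen()`).
* **Scoring** — the per-sample signature score is the unweighted mean of
  per-gene median-centered expression over the signature
  (`signature_score()`), with median-split risk stratification
  (`median_split()`) and an optional CD4-residual adjustment.
* **Survival** — Kaplan–Meier curves, log-rank tests, and Cox
  proportional-hazards fits (Efron ties, 95% Wald CIs) via the `survival`
  package behind validating wrappers (`cox_fit()`, `gene_screen()` for a
  per-gene 5-year screen with administrative censoring at 60 months).
* **Meta-analysis** — inverse-variance pooling of per-cohort log hazard
  ratios, fixed-effect or DerSimonian–Laird random-effects (`pool_hr()`):
  pooled log HR = Σwᵢyᵢ/Σwᵢ, wᵢ = 1/SEᵢ², with Cochran Q, τ² and I².
* **Synthetic data** — `simulate_tils()` and `simulate_bulk_cohort()`
  generate single-cell matrices with a planted Treg program (truncated
  Normal + logistic dropout) and bulk cohorts whose hazard is log-linear
  in a planted score, so every stage is validated against ground truth.

`run_pipeline()` chains all of it: simulate → gate → derive → score →
stratify → Cox → pool.

## Worked example

```r
library(tregsig)
p <- run_pipeline(seed = 7)

p$quadrants
#> <quadrant_stats> CD4 x LAIR2, cut-off 4, 1750 cells
#>            count percent
#> double_pos   185    10.6
#> x_only       601    34.3
#> y_only        10     0.6
#> double_neg   954    54.5

p$signature
#> <signature_gene_set> 231 genes (q < 0.001, FC >= 1.55; 185 vs 601 cells)

p$meta_score
#> <meta_result> 3 studies, fixed
#>    label log_hr      se weight
#> 1 study1 0.7310 0.08991  123.7
#> 2 study2 0.7460 0.08851  127.6
#> 3 study3 0.6637 0.08085  153.0
#> pooled HR = 2.035 (95% CI 1.846-2.243), log HR = 0.7103 (SE 0.0497)
#> heterogeneity: Q = 0.547 (df 2), tau2 = 0.0000, I2 = 0.0%
```

Reading the output: 10.6% of the 1,750 simulated TILs are CD4/LAIR2
double-positive (the generator planted an 11.4% Treg population — gating
recovers it up to dropout); the derived signature contains 231 genes; and
across three independently simulated validation cohorts the pooled hazard
ratio per unit signature score is 2.04 (95% CI 1.85–2.24), covering the
planted hazard ratio of 2. The per-cohort high-vs-low risk-group fit is in
`p$cohorts[[i]]$fit_group`:

```r
p$cohorts[[1]]$fit_group
#> <survival_fit> n = 300, events = 187, ties = efron
#>        term coef    se            hr_ci        p
#> 1 risk_high 1.04 0.156 2.84 (2.09-3.86) 2.44e-11
#> log-rank p = 3.828e-12
```

A thin command-line front end over the same functions is installed at
`system.file("scripts", "tregsig-cli.R", package = "tregsig")`, with
subcommands `simulate`, `gate`, `derive-signature`, `score`, `survival`,
`screen` and `meta` driven by YAML/JSON configs.

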