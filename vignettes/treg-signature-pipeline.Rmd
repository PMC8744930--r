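---
title: "Deriving and validating a Treg gene signature: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving and validating a Treg gene signature: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tregsig)
```

# The problem

Tumor-infiltrating regulatory T cells (Tregs) suppress anti-tumor immunity,
and their abundance in a resected tumor carries prognostic information. A
recurring analysis pattern in lung adenocarcinoma immunogenomics is:

1. in a **single-cell** RNA-seq dataset of sorted tumor-infiltrating T
   cells, identify a Treg-like subpopulation by flow-style gating on marker
   genes (here CD4 and the secreted collagen-receptor decoy LAIR2) on the
   log2(TPM+1) scale;
2. derive a **gene signature** for that population by per-gene differential
   testing against the complementary population;
3. **score** bulk tumor cohorts with the signature and split each cohort
   into high- and low-risk groups at the median score;
4. quantify the association with overall survival by Kaplan–Meier curves,
   log-rank tests and Cox proportional hazards models; and
5. **pool** the per-cohort hazard ratios into an overall estimate by
   inverse-variance meta-analysis.

`tregsig` implements each stage as a documented function, and — because the
real cohorts behind such analyses require controlled-access downloads and
preprocessing choices that are rarely fully specified — ships a synthetic
data generator that plants known ground truth at every stage, so the whole
pipeline is validated end-to-end by statistical recovery tests rather than
by re-downloading accessions.

# Gating model

A gate keeps cells with expression strictly above (`positive`) or strictly
below (`negative`) a threshold, default 4 log2(TPM+1) units; multiple gates
combine by conjunction. The strict inequality on *both* sides is
deliberate: a cell lying exactly on the threshold belongs to neither the
positive nor the negative population. Quadrant statistics
(`quadrant_fractions()`) therefore report a separate boundary count, so the
four quadrant counts plus the boundary count always sum to the total — no
cell disappears silently. Percentages are kept exact internally and
rounded to one decimal only when printed.

Because published double-positive fractions can be quoted against
different denominators (all sequenced T cells vs tumor-tissue cells only),
`quadrant_fractions()` accepts an optional `subset` argument so either
denominator can be computed explicitly.

# Signature derivation

`derive_signature()` tests every gene between the gated positive and
negative cell groups and retains up-regulated genes passing both an FDR
and a fold-change filter (defaults `q < 0.001`, `FC >= 1.55`).

Design choices, and why:

* **Welch's t-test by default.** The gated LAIR2+ group is typically a
  small minority against a large LAIR2− majority; pooled-variance t is
  unsafe under variance heterogeneity with unbalanced groups. Student's
  pooled-variance test is available via `var_equal = TRUE`.
* **Cells as replicates.** A plain two-group t-test over cells is used, not
  a pseudobulk or mixed model; that is the convention the pipeline
  reproduces and the generator's independence assumptions match it.
* **Fold change on the log2 scale.** `FC = 2^(Δ mean log2(TPM+1))`,
  because the matrix is only available in log2(TPM+1) units. A
  linear-mean variant (`fc_method = "linear_mean"`, ratio of mean
  `2^x − 1`) is exposed since some pipelines compute FC on linear TPM;
  neither is asserted as canonical.
* **Up-regulated only.** Membership additionally requires
  `mean_pos > mean_neg`: the signature is defined as genes *highly
  expressed* in the positive population.
* **Variance floor** of `1e-8` per group protects dropout-heavy genes
  whose within-group variance is numerically zero; two constant equal
  groups give `t = 0, p = 1` by convention.
* **Deterministic ordering** (ascending q, then descending FC, then gene
  id) makes the output invariant to input gene/cell order.

Benjamini–Hochberg adjustment is the standard step-up procedure (computed
via `stats::p.adjust`); the test suite checks it against a hand-written
implementation of the step-up definition on 1,000 random vectors.

`correlation_screen()` implements the companion co-expression screen: the
Pearson correlation of every gene with an anchor gene, returning the top
`top_k = 500` genes above `r_min = 0.37` — the conventional input for gene
ontology analysis of an anchor's co-expression neighborhood.

# Scoring and risk stratification

The per-sample score is the unweighted mean over signature genes of
across-sample *median-centered* expression. The phrase "across-sample
normalized" in this field is ambiguous; median-centering is its only
unambiguous component, so `normalize = "median_center"` is the default and
a z-score variant (additionally dividing by the per-gene SD) is the
explicit alternative. Genes absent from a cohort's matrix are dropped and
reported, never imputed.

`median_split()` dichotomizes at the cohort median with a fixed tie rule:
scores strictly above the median are high-risk, everything else low-risk.
The rule is deterministic and conservative for the high-risk hazard ratio;
with an odd sample count the median sample itself is low-risk.

`cd4_adjusted_score()` regresses the score on median-centered CD4
expression and returns the residual — a proxy adjustment for overall CD4+
T-cell content. How such an adjustment was done in the motivating analyses
is not specified anywhere we could follow; the residual operationalization
is one plausible reading and is flagged non-canonical in its output.

# Survival analysis

Kaplan–Meier estimation, the log-rank test and Cox regression are
delegated to the R `survival` package — the de-facto standard this class
of analysis is built on — behind thin validating wrappers:

* **Efron tie correction** by default (the `survival` ecosystem default),
  Breslow available; with no tied event times the two agree to numerical
  precision, which the tests assert.
* **Fixed-horizon endpoints** (e.g. 5-year overall survival in
  `gene_screen()`, `horizon_months = 60`) are implemented as
  administrative censoring at the horizon *before* fitting — the standard
  truncation rule.
* **Complete-case covariate handling** per fitted model, with the dropped
  count reported in the fit object. Covariate contrasts follow the usual
  lung-adenocarcinoma clinical coding: stage II vs I (higher stages coded
  missing for that contrast), female vs male, never- vs ever-smoker,
  micropapillary/solid vs acinar/papillary/lepidic pattern, age per year.
* **Monotone likelihood** (perfect separation) is refused with a classed
  error rather than reported as a huge coefficient.
* Single-gene dichotomization in `gene_screen()` defaults to the cohort
  median, the usual choice when a "high vs low" cut is otherwise
  unspecified; a continuous per-unit fit is the alternative.
* CIs are normal-theory on the log-HR scale at a fixed 95% level.

The test suite validates the Cox wrapper against a brute-force grid search
(resolution 1e-4) over an explicitly written-out Efron/Breslow partial
likelihood on small fixtures, the log-rank p-value against a
10,000-permutation null, and Kaplan–Meier output against hand
product-limit computation.

# Meta-analysis

`pool_hr()` pools per-study log hazard ratios by inverse variance.
Fixed-effect weights are `1/SE^2`; the random-effects variant uses the
DerSimonian–Laird moment estimator of the between-study variance
`tau^2 = max(0, (Q − df)/C)`. DerSimonian–Laird was chosen as the
random-effects default for its closed form and direct testability; REML
(the default of full-featured meta-analysis packages) is deliberately out
of scope, and every output records which method produced it. The tests
cross-check both methods against `metafor`.

# The synthetic-data generator

`sim_config()` + `simulate_tils()` emulate a sorted-TIL single-cell
experiment:

* four populations — a CD4+LAIR2+ Treg population, conventional CD4 cells,
  CD8 cells and an unassigned remainder — with default sizes 200 / 600 /
  800 / 150, making the Treg population ~11% of cells, the order of
  magnitude seen for CD4/LAIR2 double-positives in real TIL data;
* expression `max(0, Normal(mu, base_sd))` on log2(TPM+1)
  (`base_mean = 1.5`, `base_sd = 1`), with `CD4` elevated in both CD4
  populations, `CD8A` in the CD8 population (`marker_shift = 5`) and the
  program genes elevated only in Tregs (`program_shift = 5` by default, so
  marker-positive cells sit clearly above the gate at 4);
* logistic dropout: a value is zeroed with probability
  `plogis(dropout_rate0 − dropout_slope × mu)` (defaults 1.5 and 0.8),
  so low-mean genes drop out at ~50% while strongly expressed markers
  rarely do — the closed form makes gate-crossing fractions predictable;
* the default Treg program contains **231 genes** (FOXP3, LAIR2 and the
  tumor-Treg markers IL2RA, CTLA4, TNFRSF18, ICOS, TIGIT, CCR8, plus
  numbered `TRG` genes). The size matches the scale of the signature such
  an experiment yields; it also means the bulk cohort score, an average
  over hundreds of genes, is an essentially noiseless readout of the
  latent score, exactly as for real multi-hundred-gene signatures. A
  truncated-Normal-plus-dropout model was preferred over a
  negative-binomial count layer because the emulated data are already
  log-TPM.

`simulate_bulk_cohort()` plants survival structure: each sample carries a
latent score `s ~ N(0,1)`; signature genes gain `score_coupling × s`
(default 1) log2 units over a `Normal(8, 1)` background; survival times
are exponential with hazard
`baseline_hazard × exp(planted_beta × s + covariate effects)`
(defaults 0.015/month and `log 2` per score unit), censored by an
independent exponential (`censor_rate = 0.01`/month, non-informative by
construction — matching the Cox assumption under test; real cohorts'
censoring distributions are unpublished, so this is a configuration
choice, not an empirical value). One master seed expands into fixed
per-stage substreams so stages rerun independently and reproducibly.

What the generator does **not** emulate: patient-level batch structure,
library-size variation, doublets, gene–gene correlation beyond the planted
program, non-proportional hazards. Passing recovery tests therefore
demonstrates the estimators and the plumbing are correct under the model's
own assumptions; they are not evidence about robustness to the failure
modes real cohorts add.

# Validation problem sizes

The recovery experiments the package validates itself with use: 20
simulation seeds for signature recovery (50 planted genes at shift 1.5,
default noise and dropout; sensitivity and false-discovery proportion
measured against the planted list); 50 seeds for the null (shift 0)
type-I control; 100 replicates at n = 500 for hazard-recovery bias and CI
coverage plus 200 replicates at n = 300 under the null; 10,000 simulated
tests for the Welch type-I error; and a three-cohort end-to-end run whose
pooled hazard-ratio CI must cover the planted value. These sizes give
binomial/Monte-Carlo error comfortably inside each check's acceptance
band.

# Known limitations

* No pseudobulk or random-effect DE; cells are treated as independent.
* No time-varying covariates, stratified baselines or proportionality
  diagnostics in the Cox wrappers.
* The CD4 adjustment is a linear residual, not a causal deconvolution.
* `read_expression_matrix()` accepts any pre-normalized log2 matrix;
  probe-collapse and normalization of array cohorts are upstream of this
  package and intentionally unspecified here.
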