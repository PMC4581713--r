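---
title: "Methods: simulated evaluation of density- and GRS-augmented breast cancer risk models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulated evaluation of density- and GRS-augmented breast cancer risk models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`brcarisk` evaluates how much mammographic density and a polygenic risk
score add to a Gail-variable breast-cancer risk model, in a fully synthetic
but carefully parameterized stand-in for a Singapore mammography screening
cohort.  This vignette records the model, the generator design, the
numerical conventions, and what the package's tests do and do not establish.

## The cohort generator

### What it emulates

One row per woman, with eight categorical risk factors sampled independently
from fixed marginals: age band (50–54 / 55–59 / 60–64), ethnicity (Chinese /
Indian / Malay / Others), age at menarche (≥14 / 12–13 / <12), age at first
live birth (<20 / 20–24 / 25–29-or-nulliparous / ≥30), affected first-degree
relatives (None / ≥1), past breast biopsy (No / Yes), BMI (<20 / 20–<24 /
24–<28 / ≥28 kg/m²) and mean breast dense area (≤10 through 51–60 cm² in six
bands).  The marginals are the pooled case + non-case counts of the source
cohort (n = 24,161); the first level of each variable is the reference
category of the risk models.

Event times are exponential given covariates: hazard
`λ₀ · exp(β′x)`, with `β` fixed at the fully adjusted hazard ratios
of the source analysis (e.g. 3.37 for BMI ≥ 28, 3.27 for dense area
51–60 cm²).  Entry dates are uniform over the 29-month recruitment window
(October 1994 – February 1997); follow-up is administratively censored on
31 December 2011.  Times are recorded in whole days (event times rounded
up), which produces the tied event days typical of registry data; 10 years
is 3,652 days everywhere.  `λ₀` — events per person-year for a woman at all
reference levels — is not a free dial: `calibrate_baseline_rate()`
root-finds it so the expected event count equals the configured target, 680
(the printed 106 in-situ + 574 invasive cases).  The expectation is a
closed-form exponential probability averaged over a large fixed-seed
Monte-Carlo draw of the covariate mixture, so calibration is deterministic
given its seed.

### What it deliberately does not emulate

* **Covariate correlations.** No joint distribution was published, so risk
  factors are independent.  The real BMI–density negative confounding is
  absent; fitted coefficients on synthetic data therefore estimate their own
  generating values, not the published adjusted-vs-unadjusted shifts.
* **Baseline hazard shape.** Constant (exponential); nothing was published
  about the baseline shape, and a constant rate keeps calibration
  closed-form.  The asymmetric median follow-up between cases and non-cases
  emerges from the simulation rather than being enforced.
* **Competing mortality and dropout.** Censoring is administrative only.
* **Within-band age, screening behaviour, registry linkage.** Out of scope;
  the age band 60–64 is treated as a single category.
* Education, parity, HRT use and age at menopause appear in the source
  cohort's descriptive table but in none of the risk models, so they are not
  generated.

## Conditional genotype simulation

Genotypes are simulated *given* each woman's case status, mirroring an
analysis in which outcomes are real but genotypes must be imputed from
population data.  Controls follow Hardy–Weinberg proportions
`((1−p)², 2p(1−p), p²)`; cases follow the exponential tilt
`Q_g ∝ OR^g · P_g`, the canonical log-additive per-allele odds-ratio model.
SNPs are mutually independent and independent of all covariates (the
analysis' stated assumption; no linkage disequilibrium).  The score is
`GRS = Σ_j ln(OR_j) · g_j`.

Two consequences are worth stating because the tests rely on them:

1. `log P(case|g) − log P(non-case|g) = GRS + const`, so a logistic
   regression of case status on GRS has slope 1 per unit, and the Cox hazard
   ratio per 0.1 GRS units converges to ≈ e^0.1 ≈ 1.105 in this
   rare-disease setting.  These are emergent checks of the whole chain, not
   assertions about inputs.
2. The discrimination added by the GRS is governed by its control-group
   variance `Σ 2p(1−p) ln(OR)²`.

The published 75-SNP list is unavailable, so the shipped default panel
(`inst/extdata/snp_panel_synthetic75.tsv`) is **synthetic**: 75
(frequency, odds-ratio) pairs drawn once by `tools/make_default_panel.R`
with a fixed seed, then rescaled so the control GRS mean is 4.53 and its SD
0.37 — the location and scale implied by the published population quintile
boundaries (4.22/4.43/4.62/4.84) under normal-quantile spacing.  The panel
matches the published score's location and scale *by construction, not by
provenance*; per-SNP values carry no biological meaning.  Odds ratios land
in 1.01–1.13, typical of GWAS susceptibility loci.  A user panel in the same
TSV schema (`snp_id`, `risk_allele_freq`, `odds_ratio`) replaces it
everywhere.

Whether the population genotype frequencies behind the original simulation
were per-genotype tables or allele frequencies under Hardy–Weinberg was not
stated; Hardy–Weinberg is assumed here, and the tests verify it holds in
simulated non-cases.

## Proportional-hazards fitting and absolute risk

* **Optimizer.** `survival::coxph.fit` (the field-standard partial-likelihood
  maximizer) with the **Efron** tie approximation — day-resolution times make
  ties routine and the source analysis is silent on the choice.  The
  surrounding contract is the package's own: design encoding with fixed
  reference levels, constant-column and separation checks (a coefficient
  with standard error above 20 is rejected as separated), and the reference
  profile for baseline extraction.
* **Design encoding.** One 0/1 dummy per non-reference level
  (`variable=level` columns); GRS enters untransformed as a continuous
  column.  The base model has 15 dummies, density adds 5, GRS adds 1.
* **Baseline hazard.** The printed form of the 10-year baseline,
  `−log[S^NA(t|x̄)/(e^{β′x̄})]`, is algebraically inconsistent with
  `S = exp(−e^{β′x̄}H₀)`; the package implements
  `H₀ = −log S^NA(t|x̄) / e^{β′x̄}`, the only reading consistent with the
  model equation.  `S^NA` is the Nelson–Aalen/Efron cumulative-hazard
  estimator implemented in-package (vectorized over risk sets, matching the
  fit's tie handling) and cross-checked against `survival::basehaz` in the
  tests.  The step function is evaluated at the largest event time at or
  before 3,652 days.  `x̄` uses reference categories for categorical terms
  (so `e^{β′x̄} = 1` in categorical-only models) and the cohort mean for the
  GRS.
* **Absolute risk.** `r = 1 − exp(−e^{β′x}·H₀(10y))`, increasing in the
  linear predictor; mean predicted risk matches the empirical 10-year
  cumulative incidence (calibration-in-the-large) up to the
  reference-profile approximation.
* **PH diagnostics.** `schoenfeld_ph_check()` wraps `survival::cox.zph`
  (scaled Schoenfeld residuals against Kaplan–Meier-transformed time); the
  tests verify both its size under exact proportional hazards and its power
  against a sign-flipping effect.

## Evaluation conventions

* **Labels.** ROC/AUC and predictive values use the 10-year case label
  (event within 3,652 days), consistent with scoring by 10-year absolute
  risk; the label horizon of the source analysis was unstated.  Under the
  default calendar every woman has ≥ 10 years of potential follow-up, so the
  label is never censored.
* **Cross-validation.** Folds are stratified by event status so every
  training set contains events; out-of-fold risks are pooled before one AUC
  is computed per replicate.  "Averaging the ROCs" over genotype replicates
  means averaging AUCs, and pointwise-averaging curves on a fixed
  false-positive grid for plotting; intervals are 2.5/97.5 percentiles
  across replicates.
* **AUC.** Mann–Whitney with half credit for ties, computed from ranks; the
  tests pin it to an independent implementation (pROC) and to hand-counted
  examples.
* **Concordance.** The Gönen–Heller estimator
  `K = 2/(n(n−1)) Σ_{i<j} 1/(1+e^{−|Δ_ij|})`, `Δ_ij = β′(x_i−x_j)`, with
  exchangeable pairs contributing ½, computed in C++ (O(n²) pairs, ~1.5 s at
  n = 24,161) and checked against a brute-force R double loop; optional
  percentile interval by a nonparametric bootstrap over subjects (200
  resamples by default).
* **Predictive values.** `PPV(τ) = #(case ∧ r ≥ τ)/#(r ≥ τ)` and
  `NPV(τ) = #(non-case ∧ r < τ)/#(r < τ)`; empty groups yield `NA`, never 0.
  The a-priori thresholds are 1.0–3.0% in half-point steps plus 5% and 10%;
  values at the top two thresholds rest on few women and are unstable, a
  caveat the source analysis itself makes.
* **Quintiles.** Rank-based with stable ties (a tied block takes the
  quintile of its smallest rank; a constant score vector is all quintile 1),
  computed on the pooled cohort.

## Reproducibility and problem sizes

Every random draw descends from one master seed through named substreams
(`derive_seed(seed, "genotypes/rep7")` and the like), recorded in the run
manifest, so any replicate is regenerable in isolation and seeded reruns
write byte-identical CSV artifacts.  The full profile (`paper_profile.yaml`)
uses 1,000 genotype replicates and 10-fold cross-validation.  The package's
own test and acceptance runs use the full cohort size (n = 24,161) with 20
genotype replicates, 20 master seeds for the AUC-ladder comparison, 50
replicates for coverage checks, and 3 replicates per seed where only paired
AUC gaps are needed — chosen so the Monte-Carlo error of each reported mean
is several times smaller than the tolerance it is compared against.

## What passing tests do and do not show

On synthetic cohorts the fitted models are correctly specified (covariates
independent, proportional hazards exact, genotypes exactly log-additive), so
the package's headline numbers — CV AUC ≈ 0.63/0.66/0.68 across the three
nested models, concordance ≈ 0.66, GRS hazard ratio ≈ 1.10 per 0.1 units —
demonstrate that the *pipeline* recovers the published operating
characteristics when fed the published distributions and effect sizes.  They
do not validate the model on real data: real covariate correlation, density
measurement error, linkage disequilibrium, ethnicity-specific allele
frequencies and non-proportional effects are all outside the generator.
Known limitations worth keeping in mind when transferring conclusions:
orthogonal simulated genotypes can flatter the incremental AUC of the GRS,
and PPV differences at tail thresholds carry large sampling error even at
n = 24,161.
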