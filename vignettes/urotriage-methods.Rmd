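---
title: "Methods: urinary biomarker risk models for prostate biopsy triage"
author: "urotriage authors"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Methods: urinary biomarker risk models for prostate biopsy triage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(urotriage)
```

# The clinical problem

Men with a raised serum PSA (>= 4 ng/mL) or an adverse digital rectal
examination (DRE) are conventionally referred for a trans-rectal
ultrasound-guided (TRUS) prostate biopsy. Most of these biopsies find either
no cancer or indolent Gleason 6 disease, so a non-invasive test that ranks
patients by their risk of harbouring clinically significant cancer (Gleason
>= 3+4, and especially >= 4+3) can spare many men an invasive, stressful and
complication-prone procedure.

`urotriage` implements a complete, reproducible modelling pipeline for this
triage problem, built around three urinary information sources measured on a
single post-DRE urine sample:

* **clinical variables** — age, serum PSA, the clinician's DRE prostate-size
  impression, and collected urine volume;
* **EN2 protein** — an ELISA measurement of the Engrailed-2 transcription
  factor, secreted by prostate cancer cells into urine;
* **cell-free RNA (cf-RNA)** — raw NanoString-style counts for 167
  gene-probes from urinary extracellular vesicles, plus internal
  positive-control probes.

Four comparator variable sets are modelled throughout: `SoC` (clinical
only), `Engrailed` (EN2 only), `ExoRNA` (cf-RNA only) and `ExoGrail` (all
172 candidate predictors).

# Pipeline overview

1. **Exclusions** (`applyExclusions`): patients with a prostate biopsy or
   TURP fewer than 6 weeks before sampling, a positive bone scan, or
   PSA > 100 ng/mL (metastatic signature) are removed and logged.
2. **Normalisation** (`normaliseCounts`): each sample's probe counts are
   scaled by `reference / geomean(positive controls)`, where the cohort
   reference is the geometric mean of the per-sample positive-control
   geometric means, then transformed `log2(x + 1)`.
3. **Training label** (`assignTrainingLabel`): biopsy outcome is mapped to a
   continuous scale L — no evidence of cancer 0, Gleason 6 and 3+4 0.5,
   Gleason >= 4+3 1 — acknowledging that two patients with the same TRUS
   Gleason score do not share identical tumour composition. L is used only
   for training; every evaluation uses the categorical outcome.
4. **Feature selection** (`stabilitySelect`): Boruta runs on B bootstrap
   resamples; features confirmed in >= 90% of resamples are retained.
5. **Risk models** (`trainRiskModel`, `oobScores`): a 401-tree regression
   forest on L, per-tree subsampling of 63.2% of patients without
   replacement; each patient's risk is the mean prediction of the trees
   that did not train on them (out-of-bag), so the development cohort is
   scored without a held-out split.
6. **Evaluation** (`auc`, `aucCI`, `aucDifferenceTest`,
   `proportionalOddsOR`, `meanDiffBCa`): discrimination at three binary
   endpoints with stratified bootstrap intervals, paired bootstrap AUC
   tests, ordinal (proportional-odds) effects and BCa effect sizes.
7. **Decision-curve analysis** (`dcaCurves`, `biopsyNetReduction`):
   standardised net benefit across decision thresholds, computed on
   resamples reweighted to a general biopsied population, and the implied
   net reduction in biopsies.

`runPipeline()` wires these together under one root seed; every stage
derives its own stream deterministically, so a rerun is bit-identical and
stages can be re-run in isolation.

# Boruta with bootstrap stability selection

Boruta decides, feature by feature, whether a predictor carries more
information about the label than chance. At each iteration every undecided
feature gets a *shadow*: a permuted copy that preserves its marginal
distribution but breaks its link to the label. A regression forest is grown
on real plus shadow features and permutation importance (increase in
out-of-bag squared error) is recorded. A feature scores a *hit* when it
outranks the most important shadow. After `i` iterations the hit count is
compared with Binomial(i, 1/2) through its normal approximation: features
significantly above chance (one-sided p <= 0.01) are Confirmed, those below
are Rejected and dropped. Features still undecided at `maxIter` stay
Tentative and count as not-selected — a deliberately conservative choice, as
is the inclusive `>=` at the 90% retention boundary.

Implementation details that matter:

* Shadows are rebuilt every iteration; at least five are kept (cycling over
  the undecided features) so the max-shadow benchmark stays stable when few
  features remain. Confirmed features remain in the forest but no longer
  receive shadows.
* Shadow permutation seeds are keyed by feature name, and columns are
  processed in a canonical order, so decisions are invariant to the order
  features are supplied in.
* **Resampling-aware shadows.** Stability selection runs Boruta on
  bootstrap resamples, which contain duplicated patients. A naive row
  permutation would give shadows *less* ability to memorise the label
  through duplicates than real columns have, biasing every feature towards
  confirmation. Shadows are therefore permuted across *distinct source
  patients*, duplicates receiving identical shadow values, which restores
  the real-versus-shadow exchangeability of null features. Without this the
  null control fails badly (in development, 49 of 50 noise probes were
  spuriously retained).
* The resample schedule depends only on the sample count and the seed, so
  all four variable sets are selected and trained on identical resamples.

The reported importance is a Z-score of a feature's permutation importance
against the shadow-importance distribution of the same iteration, averaged
over the iterations the feature was undecided.

# Risk scores from out-of-bag predictions

Forests use the conventional regression defaults: `mtry = floor(p/3)`
(minimum 1), minimum node size 5, and 401 trees; per-tree in-bag sets hold
`floor(0.632 n)` patients drawn without replacement — the without-replacement
counterpart of a bootstrap-sized sample — and are generated explicitly from
the shared seed, so variants see identical resamples. With 401 trees each
patient is out of bag in about 148 trees; their risk score is the equally
weighted mean of those trees' predictions and, because leaves average a
label in {0, 0.5, 1}, lies in [0, 1]. A patient in bag in every tree (only
possible in degenerate, few-tree forests) is flagged and excluded from
metrics. The single-feature `Engrailed` forest is effectively a bagged
stump ensemble; it is trained with the same machinery.

# Evaluation

* **Endpoints**: any cancer, Gleason >= 3+4, Gleason >= 4+3; unbiopsied NEC
  and biopsy-negative patients are negatives everywhere.
* **AUC** is the Mann–Whitney concordance probability with ties counted
  one-half, computed from midranks; confidence intervals use 1000
  stratified bootstrap resamples (positives and negatives resampled
  separately) with inverse-ECDF percentile bounds at 2.5/97.5%.
* **AUC differences** between models on the same patients use a paired,
  class-stratified bootstrap; the two-sided p-value comes from the normal
  approximation (mean/SD) of the resampled difference distribution.
* **Ordinal effect**: a proportional-odds regression of the graded outcome
  — no cancer, Gleason 6, Gleason 3+4, Gleason >= 4+3 — on the risk score,
  reported as an odds ratio per 0.1 risk increase with a delta-method Wald
  interval. Whether "no cancer" should be split into unbiopsied NEC versus
  biopsy-negative is genuinely open; the pooled four-level grading is used
  because the risk-distribution figures distinguish exactly these four
  colour classes, and the split is exposed through `.ordinalGrade` should
  users want it.
* **Effect sizes**: mean risk differences between outcome groups use a
  bias-corrected and accelerated (BCa) bootstrap with 1000 resamples; the
  bias correction comes from the position of the observed difference in
  the resample distribution and the acceleration from jackknife skewness
  over all observations. Degenerate cases collapse gracefully (constant
  groups give a zero-width interval; singleton groups fall back to
  percentile bounds with a warning).

# Decision-curve analysis

Net benefit at decision threshold $p_t$ is
$NB = TP/n - (FP/n)\,p_t/(1-p_t)$; standardised net benefit divides by
prevalence so 1 means perfect triage and 0 matches biopsying no one.
Because a development cohort over-represents cancer relative to the
population that would actually face the biopsy decision, curves are
computed on stratified bootstrap resamples reweighted to the outcome mix of
the control arm of a large PSA-testing trial: 60.6% no cancer, 23.6%
Gleason 6, 8.7% Gleason 7, 7.1% Gleason >= 8, drawn as 1000 resamples of
197 patients (largest-remainder rounding gives fixed per-resample strata of
119/47/17/14). The Gleason 7 stratum pools 3+4 and 4+3 patients and draws
uniformly from the pool, preserving their cohort ratio in expectation — the
source reports only a combined Gleason 7 fraction.

The net reduction in biopsies from adopting a model instead of a reference
strategy is $(NB_{model} - NB_{ref})(1 - p_t)/p_t$, reported per 100
patients. Both natural references are provided: treat-all (biopsy every
patient with PSA >= 4 ng/mL) and the SoC model; `reductionCurves()`
defaults to treat-all.

# The synthetic cohort generator

No patient-level data ship with the package; `generateCohort()` draws
cohorts with the statistical structure the analysis assumes, and its
defaults emulate the published development cohort:

* class counts 25 NEC / 52 biopsy-negative / 30 Gs6 / 48 Gs3+4 / 24 Gs4+3 /
  28 Gs>=8 (n = 207), with optional metastatic extras (bone-scan positive,
  PSA > 100) for exercising the exclusion rules;
* PSA and EN2 are log-normal per class — strictly positive, right-skewed
  markers — with PSA location/scale moment-matched to the published
  median/IQR summaries (no-cancer 6.10 (3.70–8.80), cancer 10.35
  (6.82–16.48) ng/mL; `sdlog = log(q75/q25)/1.349`), NEC truncated below
  4 ng/mL by definition and non-metastatic PSA truncated below 100;
* age is normal per cancer status (65.2 ± 8.1 vs 69.7 ± 7.7 years); DRE
  size is categorical with the published proportions, "Unknown" kept as an
  explicit level;
* cf-RNA counts are negative-binomial (dispersion 2) on the raw count
  scale, baseline log2 means uniform in [4, 9], with planted log2 shifts on
  informative probes; the default panel plants 11 probes — the size of the
  published cf-RNA signature — with a monotone grade profile reaching +2
  log2 in the highest class;
* every count, positive controls included, is multiplied by a per-sample
  log-normal lane factor (sdlog 0.3) that positive-control normalisation
  is designed to remove; positive controls sit at six fixed expected
  levels spanning 16–16384 with low dispersion.

The per-probe count families and EN2 scale are stated assumptions — the
source reports no per-probe distributions — and are fully exposed in
`cohortDesign()`. The generator does not emulate assay chemistry, batch or
inter-site effects, probe–probe correlation beyond the shared lane factor,
or missingness; passing tests therefore demonstrate correctness of the
machinery and recoverability of planted signal under clean conditions, not
clinical performance on real data. Reproducing the published real-data AUCs
requires the deposited cohort and is out of scope here.

# Numerical and scale choices

* Pseudocount 1 before log2: urinary cf-RNA counts contain zeros.
* The cohort normalisation reference is the *geometric* mean of per-sample
  geometric means, making the two-sample worked example (geomeans 4 and 16
  give reference 8, factors 2 and 0.5) exact. Scale invariance to a common
  per-sample factor holds exactly against a fixed reference and up to a
  vanishing `log2(c)/n` shift otherwise.
* EN2 and PSA enter untransformed: tree models are invariant to monotone
  transforms of single features.
* Test-suite problem sizes are scaled-down study conditions chosen once:
  stability-selection checks run B = 100 resamples (vs 1000) on 50-probe
  panels with reduced internal forests (100–150 trees) and capped
  iterations (30–50; the earliest possible decision at alpha = 0.01 is
  iteration 7); coverage checks use 200 trials. Planted multi-probe panels
  mix grade-response profiles, since identically responding probes are
  mutually redundant and redundancy cancels permutation importance. The full-scale defaults (B = 1000, 401 trees,
  maxIter = 100) remain the package defaults.
* All bootstrap machinery (resample schedules, in-bag sets, shadow
  permutations) derives from one root seed via deterministic sub-seed
  hashing; results are bit-reproducible and independent of the caller's
  RNG state.

# Known limitations

* The Z-approximation of the binomial hit test is applied without
  multiplicity correction, matching the source's plain p <= 0.01 rule;
  with very many features a familywise-corrected variant would be more
  conservative.
* OOB risk scores are in-cohort estimates; they avoid optimism from
  resubstitution but are not a substitute for external validation.
* The proportional-odds model assumes a common slope across outcome splits;
  no formal test of that assumption is run.
* `capResample` requires every target stratum to be non-empty in the source
  cohort; it reweights but cannot extrapolate.
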