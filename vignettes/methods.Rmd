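---
title: "Normative w-score analysis of tau-PET positive grey matter: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normative w-score analysis of tau-PET positive grey matter}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tauvbm)
```

## The scientific problem

Retired contact-sport athletes are at risk of chronic traumatic
encephalopathy (CTE), a tauopathy for which no validated antemortem
biomarker exists. A natural question is whether regional tau-PET signal in
athletes who are *negative* for Alzheimer-type pathology coincides with
grey-matter atrophy and with cognitive performance. `tauvbm` implements
that analysis chain as a reusable, fully tested pipeline:

1. **Biofluid gating** — exclude athletes whose plasma p-tau181 or CSF
   panel indicates Alzheimer-type pathology, so any remaining tau signal
   is not driven by AD.
2. **SUVR positivity** — scanner-harmonised smoothing of SUVR images,
   thresholding at 1.30 SUVR, and % positivity in grey matter, globally
   and per atlas region.
3. **Normative w-scores** — a voxelwise age + TIV regression fit on
   healthy controls; each athlete's grey-matter map is converted to
   w-scores (covariate-adjusted z-scores) against that model.
4. **Inference** — a paired t-test of mean w in tau-positive vs
   tau-negative voxels, quartile spatial analyses, and partial Pearson
   correlations of neuropsychological composites with tau burden, with
   BCa bootstrap intervals and Bonferroni adjustment.

Because the underlying human imaging data are not publicly available, the
package ships a synthetic cohort generator with known ground truth; every
stage is validated against that truth and against brute-force oracles.

## The normative model

For voxel $v$, control grey-matter values are modelled as

$$ y_{iv} = \beta_{0v} + \beta_{a v}\,\mathrm{age}_i + \beta_{t v}\,\mathrm{TIV}_i + \varepsilon_{iv}, \qquad \varepsilon_{iv} \sim (0, \sigma_v^2), $$

fit by ordinary least squares independently per voxel (no spatial
regularisation). An athlete's w-score at voxel $v$ is

$$ w_v = \frac{y^{\mathrm{obs}}_v - \hat y_v(\mathrm{age}, \mathrm{TIV})}{\hat\sigma_v}, $$

so $w \approx \mathcal N(0,1)$ for a healthy subject and lower $w$ means
less grey matter than expected for the subject's age and head size.
Numerical choices:

* **Residual SD denominator** is $n-3$ (unbiased under the 3-parameter
  model). The source analysis does not state its convention; at $n = 54$
  controls the difference to $1/n$ is below 3%.
* **Covariates are centred/scaled internally** for conditioning.
  W-scores are provably invariant to any affine covariate recoding, and a
  regression test enforces invariance at 1e-8; `coef()` reports
  coefficients back on the natural scale (GM units per year / per mL).
* **SD floor**: voxels with $\hat\sigma_v < 10^{-6}$ GM units would
  amplify rounding noise through the division and are set missing in
  w-score maps (configurable via `sd_floor`).
* **Extrapolation guard**: covariates outside the control range (widened
  by 10% per side) trigger a warning, never a silent score.
* Subjects whose tau-positive mask is empty contribute no paired
  observation; the paired test drops them and the count is reported.

`fit_normative()` returns a classed model object with `print`, `summary`,
`coef`, `predict` (expected map or w-score map) and `simulate`
(control-like draws) methods.

## PET processing

* **Frame averaging** weights each frame by its overlap with the
  reconstruction window (80–100 min, or 80–90 min for short scans); an
  unweighted mean is available by flag. Uncovered windows are an error
  that names the gap.
* **SUVR** divides by the mean activity in the reference-region mask
  (inferior cerebellar grey matter in the source protocol; here any mask
  on the common grid).
* **Smoothing** is separable Gaussian with scanner-specific anisotropic
  FWHM — 6.55 × 6.55 × 7.75 mm (PET/CT) and 7.37 × 7.37 × 7.91 mm (HRRT)
  — equalising effective resolution across scanners;
  $\sigma = \mathrm{FWHM}/\sqrt{8\ln 2}$ per axis. At the volume edge and
  at missing/out-of-mask voxels the truncated kernel is renormalised over
  its in-support weights (normalised convolution), so constants are
  preserved and boundary SUVR is not attenuated; SPM-style zero padding
  is available via `boundary = "zero"`. Smoothing happens **before**
  thresholding; a regression test pins the order.
* **Threshold comparator**: the positivity threshold is 1.30 SUVR with
  "$\ge$" by default. The source material states the rule both as
  "> 1.30" and "≥ 1.30" in different places; the comparator is explicit
  (`cmp`) and affects only exact-boundary voxels.
* **% positivity** is reported on the 0–100 scale
  (`100 · positive / grey-matter voxels`), per subject and per atlas
  region; regions without grey-matter voxels report missing, never 0.
* Motion and partial-volume correction are upstream concerns: inputs are
  assumed corrected, and the pipeline neither registers nor resamples —
  mismatched grids are a hard error, because silent resampling corrupts
  voxel counts.

## Biofluid gate

Thresholds (all strict inequalities, configurable):

| Assay | Rule |
|---|---|
| plasma p-tau181, in-house Simoa | > 10.5 pg/mL if age < 60; > 13.3 pg/mL if age ≥ 60 |
| plasma p-tau181, Advantage V2 kit | > 2.2 pg/mL |
| CSF triplet | p-tau > 68 pg/mL **and** Aβ42/t-tau index < 0.8 |

The Aβ42/t-tau index formula is not uniquely standardised; the default is
the widely used discriminant $A\beta_{42} / (240 + 1.18\,t\text{-}tau)$
and the function is pluggable (`index_fn`) so an alternative can be
configured rather than silently assumed. A subject positive on *any*
modality at *any* visit is excluded (conservative reading of combined
plasma/CSF screening), and the report records which rule fired.
`example_screening_cohort()` reproduces the reference screening scenario:
52 athletes, four plasma positives (13.18 pg/mL in-house under the
age < 60 rule; 7.4, 2.8, 2.5 pg/mL on the V2 kit) and one tau-PET
AD-pattern flag, leaving 47. The in-house positive at 13.18 pg/mL is only
positive under the age < 60 threshold; the worked cohort assigns that
subject age 55 accordingly.

## Neuropsychological composites

Composites average normed scores within domain; higher is always better.

* **Memory** (z): mean of RAVLT trials 1–5, RAVLT long-delay recall and
  RVDLT trials 1–5 (a 2-test RAVLT/RVDLT variant is available by flag).
* **Speed/attention** (z): mean of TMT-A, digit span forward, Stroop
  colour and word, SDMT written and oral.
* **Executive** (t): the four WCST t-scores are averaged first, then that
  average, digit span backwards and TMT-B are averaged — the WCST battery
  carries the weight of one element. The composite stays on the t scale;
  z and t scales are never mixed, and no cross-scale conversion is
  applied because composites are used only as correlates.

Missing-data floors (2 of 3 memory, 4 of 6 speed, all three executive
elements with ≥ 3 WCST scores) are a package design choice to keep
composites stable under sparse batteries; below the floor the composite
is missing, never an exception. Whether digit span backwards belongs
inside the executive mean is ambiguous in the source description; it is
included as a third element, which the weight-structure test documents.

## Quartile spatial analysis

Global % positivity is rank-split into four ordered groups (quartile 1 =
lowest). When $n \bmod 4 \ne 0$ the larger groups go to the *lower*
quartiles, and ties break by stable subject-id order with a logged
notice — both choices are deterministic and documented because no
standard fixes them. At $n = 47$ the sizes are 12/12/12/11. Per-quartile
mean SUVR images support visualisation; the regional analysis regresses
per-subject positive-voxel extent (count by default; % by choice) on the
numeric quartile index and age — quartile enters as a 1–4 numeric trend,
matching the "increase across quartiles" framing — optionally plus
scanner and scan-duration covariates (on by default). The quartile
coefficient gets a within-quartile-stratified BCa CI and a Bonferroni
correction whose family is the number of regions tested in the run.

## Statistics

* **Paired t**: $t = \bar d / (s_d/\sqrt n)$ on complete pairs,
  two-sided p on $n-1$ df; zero-variance differences are flagged as
  degenerate rather than producing infinite t.
* **Partial Pearson correlation**: x and y are residualised on
  [1, covariates] by least squares and the residuals correlated;
  $p$ from $t = r\sqrt{df/(1-r^2)}$, $df = n - 2 - k$. Scanner and
  scan-window are coded 0/1; partial correlation is invariant to affine
  recoding, so the coding is immaterial (property-tested at 1e-10).
  A variable explained exactly by the covariates has partial correlation
  0 by definition; the implementation detects numerically zero residuals
  rather than correlating rounding noise.
* **BCa bootstrap**: bias correction $z_0$ from the bootstrap CDF at the
  point estimate, acceleration from the jackknife skewness formula,
  endpoints by order-statistic interpolation on the normal-quantile scale
  at rank $(B+1)p$. Resampling is stratified when strata are given
  (stratum sizes preserved); the jackknife for the acceleration pools
  observations across strata. Resamples where the statistic is undefined
  are redrawn (more than 10% redraws is an error), every call takes an
  explicit seed, and forcing $z_0 = a = 0$ reduces the interval exactly
  to the percentile interval — a tested identity. Repetition counts
  default to 2000 for the paired contrast and regional regressions and
  1000 for the correlation table, both per-call parameters.
* **Bonferroni** always takes an explicit family size.

## The synthetic cohort generator

The generator is first-class, tested code; its defaults *are* the study
conditions the validation suite runs under.

* **Cohorts**: 54 controls (ages uniform 26–71; TIV normal 1500 ± 120 mL)
  and 47 athletes; athletes get scanner labels at 66% PET/CT / 34% HRRT
  and 80–100 min windows at 78.7%, education 15 ± 2 years. Athlete ages
  are drawn on the control range so the normative model is never
  extrapolated in the default study (real cohorts extend further; the
  extrapolation guard exists for that case).
* **Grey matter**: a fixed smooth template (low-frequency sines/cosines of
  voxel coordinates — not a brain; nothing is ever downloaded) plus
  linear age (−0.002 GM units/year) and TIV (2e-4 GM units/mL) effects
  plus voxelwise Gaussian noise (σ = 0.05). The grey-matter mask is the
  template's interior (> 0.35).
* **Tau**: SUVR = 1.0 + severity × (sum of compact radial-cosine
  hotspots) + noise (σ = 0.05). Hotspots sit anterior/laterally to echo a
  frontotemporal pattern — placement is cosmetic; the coupling structure
  is what tests need. Per-subject severity ~ U(0.8, 1.8) is what spreads
  % positivity across the cohort and drives the quartile structure.
* **Coupling**: athlete GM = control-model prediction + global atrophy
  offset (−0.015 ± 0.02 GM units across subjects) + coupling_beta ×
  max(SUVR excess, 0) + noise, with coupling_beta = −0.005 GM units per
  SUVR. Atrophy tracks the *noise-free* tau burden: measurement noise
  belongs to the PET channel, not to anatomy. The offset and coupling
  defaults were fixed once so that the athlete w-contrast lands near the
  reference magnitudes (≈ −0.37 ± 0.4 in tau-positive vs −0.31 ± 0.37 in
  tau-negative grey matter); the between-subject offset SD moves both
  means equally and cancels exactly in the paired difference.
* **Memory**: the memory composite equals −0.03 z per % positivity plus
  N(0, 0.5) noise (test-level scores are jittered around the composite
  with centred noise, so the construction is exact); speed and executive
  batteries are drawn independently of tau, mirroring null domains.
* **Biofluids**: each subject gets one assay route at roughly the
  cohort's observed mix (30% in-house / 38% V2 / 32% CSF); positives are
  placed 5–40% above the applicable threshold, negatives 5–50% below, and
  the generator's labels are the truth the gate is checked against.

What the generator does **not** emulate: real anatomy and folding,
scanner noise physics (spatially correlated noise, partial-volume
bleeding), nonlinear age effects, site/batch effects, longitudinal
change, and realistic missingness in the neuropsych battery. Passing
tests therefore certify the *computational* chain — formulas, masks,
counts, calibration of the statistics under the generator's assumptions —
not robustness to those real-data complications.

## Validation design and problem sizes

The suite validates every operation three ways: frozen closed-form
examples, brute-force oracles (exhaustive voxel loops on ≤ 8³ volumes
across 100 seeded trials, closed-form normal-equation solves, the
textbook partial-correlation recursion, a reference bootstrap
implementation), and ground-truth recovery on the generator. Problem
sizes were chosen so the full suite runs in minutes on one core: a 16³
grid at 2 mm for study-scale runs, 12³ for unit-scale runs, 100 power
replicates and 500 null replicates for the end-to-end operating
characteristics, and 1,000 Monte-Carlo repeats at 2,000 resamples for
BCa coverage. At these sizes the relevant standard errors are far below
the margins asserted.

## Known limitations

* **The paired contrast shares one normative model.** All athletes are
  scored against a single model estimated from ~54 controls, so model
  estimation error is shared across subjects and correlates the
  per-subject (tau-positive − tau-negative) differences. Under the
  generator's null (no tau–atrophy coupling) the paired t-test rejects at
  about 0.15 instead of 0.05 at this control sample size; with several
  hundred controls the rate returns to nominal. The package reproduces
  the design faithfully rather than hiding the effect; the corresponding
  calibration check documents it, and the memory partial correlation —
  whose covariates are subject-level — is calibrated (≈ 0.05) under the
  same null. Interpret paired p-values from small control cohorts with
  this in mind.
* BCa coverage for a mean of n = 30 normal draws measures ≈ 0.93 at the
  nominal 95% — the well-known small-sample undercoverage of BCa, at the
  edge of its acceptance band here.
* Voxelwise OLS ignores spatial correlation; w-score maps are valid
  marginally per voxel, and all inference here aggregates them into
  subject-level means before testing.
* The pipeline refuses, rather than fixes, mismatched grids; registration
  must happen upstream.

## Reproducibility

Every stochastic component takes a seed: the generator derives
per-component streams from `sim_config(seed=)`, and every bootstrap call
requires its own seed. `run_pipeline()` is bit-reproducible given its
config and emits a manifest (config snapshot, seeds, package version,
per-stage effective n) sufficient to re-execute the run.

```{r example, eval = FALSE}
library(tauvbm)
report <- run_pipeline(sim_config(seed = 1))
report
```
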