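# tauvbm

Voxelwise normative w-score analysis of tau-PET positive grey matter.

`tauvbm` is an R implementation of the analysis chain used to ask whether
regional tau-PET signal in Alzheimer-biomarker-negative cohorts (for
example, retired contact-sport athletes at risk of chronic traumatic
encephalopathy) coincides with grey-matter atrophy and with memory
performance. It is written for neuroimaging analysts who have
preprocessed, spatially normalized grey-matter maps and SUVR (or PET
frame) images on a common grid, and who want the downstream statistics —
biofluid gating, positivity masks, normative w-scores, quartile spatial
analysis, bootstrap inference — as tested, reusable, seed-reproducible
functions rather than a one-off script.

## The model

For each voxel $v$, grey-matter values in healthy controls are regressed
on age and total intracranial volume (TIV):

$$ y_{iv} = \beta_{0v} + \beta_{av}\,\mathrm{age}_i + \beta_{tv}\,\mathrm{TIV}_i + \varepsilon_{iv} $$

An athlete's **w-score** at voxel $v$ is the covariate-adjusted z-score

$$ w_v = \frac{y_v^{\text{obs}} - \hat y_v(\text{age}, \text{TIV})}{\hat\sigma_v}, $$

where $\hat\sigma_v$ is the controls' residual SD (denominator $n-3$).
Lower $w$ means less grey matter than expected for age and head size.
Tau-positive voxels are grey-matter voxels with SUVR ≥ 1.30 after
scanner-specific Gaussian smoothing (FWHM 6.55×6.55×7.75 mm for PET/CT,
7.37×7.37×7.91 mm for HRRT); **% positivity** is
100 · positive / grey-matter voxels. The headline inferences are a paired
t-test of mean w inside vs outside the tau-positive mask, and partial
Pearson correlations (controlling age, education, scanner, scan duration)
of memory / speed / executive composites with tau burden, with BCa
bootstrap CIs and Bonferroni adjustment.

Because the motivating human data are not public, the package includes a
synthetic cohort generator (`sim_config()`, `generate_controls()`,
`generate_athletes()`, ...) with known ground truth, and the whole chain
is validated against it plus brute-force oracles.

## Worked example

Run the full synthetic study — cohort simulation, AD-biomarker gate, PET
smoothing/thresholding, normative fit, w-score extraction, quartiles,
composites, inference — from one seed:

```r
library(tauvbm)
report <- run_pipeline(sim_config(seed = 1), regions = FALSE)
report
```

```
== Synthetic tau-PET / w-score study report ==
Gate: 47 screened, 0 excluded, 47 analyzed
Global % positivity: median 30.45% (range 15.16-41.76)
Paired w-score contrast (tau+ vs tau-):
  Paired t: n = 47, mean diff = -0.03345 (-0.2953 vs -0.2618), t = -3.745, p = 0.0005002
  BCa CI of the mean difference: [-0.0511, -0.01687]
Quartiles: <quartile_assignment> n = 47, sizes 12/12/12/11, cuts at 23.54, 30.49, 38.7 %
Composite ~ tau partial correlations:
  composite    tau_measure       r  n   p_raw  ci_lo   ci_hi p_bonferroni
1    memory pct_positivity -0.4737 47 0.00134 -0.656 -0.1892      0.00801
2    memory        gm_suvr -0.4539 47 0.00223 -0.627 -0.1609      0.01339
3     speed pct_positivity -0.2326 47 0.13333 -0.458  0.1076      0.80001
4     speed        gm_suvr -0.2184 47 0.15935 -0.450  0.0835      0.95609
5 executive pct_positivity -0.1130 47 0.47061 -0.438  0.2226      1.00000
6 executive        gm_suvr -0.0922 47 0.55644 -0.417  0.2356      1.00000
```

Reading this: the 47 simulated athletes have *lower* grey-matter w-scores
inside their tau-positive voxels than outside (mean difference −0.033 w
units, paired p = 5e-4, BCa 95% CI excluding zero) — tau-marked tissue
carries more atrophy than tau-free tissue in the same brains. The memory
composite falls with tau burden (partial r ≈ −0.47 against % positivity,
Bonferroni-adjusted p = 0.008) while the speed and executive composites —
generated independent of tau — stay null, exactly as the ground truth
prescribes.

Individual stages are plain functions if you bring your own data:
`load_volume()` / `load_subject_table()`, `apply_gate()`,
`average_frames()` → `compute_suvr()` → `smooth_volume()` →
`threshold_positivity()` → `percent_positivity()`,
`fit_normative()` → `wscore_map()` → `extract_mask_means()`,
`assign_quartiles()` / `region_extent_regression()`, and
`paired_t()` / `partial_pearson()` / `bca_ci()` / `bonferroni()`.

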