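Package: tauvbm
Title: Voxelwise Normative W-Score Analysis of Tau-PET Positive Grey Matter
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Links tau-PET positivity to grey-matter atrophy and memory in
    AD-biomarker-negative cohorts. Provides plasma/CSF biomarker gating,
    voxelwise age+TIV normative models with w-score maps, SUVR computation
    with scanner-specific smoothing and positivity thresholding, quartile
    spatial analysis, neuropsychological composites, and the accompanying
    inferential toolkit (paired t-tests, partial Pearson correlations,
    bias-corrected accelerated bootstrap intervals, Bonferroni adjustment),
    together with a fully parameterised synthetic cohort generator with
    known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    boot,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
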