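Package: cpseg
Title: Choroid Plexus Volumetry and Cohort Statistics from Structural MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segments the choroid plexus of the lateral ventricles from
    T1-weighted structural MRI given a FreeSurfer-style anatomical label
    volume, using two-stage univariate Gaussian-mixture intensity
    clustering with edge-preserving (SUSAN) smoothing between the stages,
    and computes voxel-count volumes in cubic millimetres.  Includes a
    synthetic brain-phantom generator with exact ground truth for
    validating the segmentation, a clinical cohort simulator calibrated
    to target group summaries and partial correlations, and the
    downstream statistical workflow for choroid-plexus studies: the
    CSF/serum albumin quotient, disease progression rate,
    covariate-adjusted general linear model group comparisons with
    family-wise error corrected post hoc contrasts, partial correlations,
    and summary-statistic t/ANOVA/chi-squared tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    RNifti,
    jsonlite,
    rlang,
    stats,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
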