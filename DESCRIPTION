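Package: petivimdki
Title: Simulation and Statistical Analysis of PET-IVIM-DKI Biomarkers for
    Lymphovascular Invasion Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward and inverse models for multi-b-value diffusion MRI
    (mono-exponential ADC, bi-exponential intravoxel incoherent motion,
    diffusion kurtosis imaging) with Rician noise simulation, synthetic
    FDG-PET lesion volumes with isocontour volume-of-interest metrics
    (SUVmax, metabolic tumor volume, total lesion glycolysis), a
    quantile-calibrated two-group cohort generator with two-reader
    replicates, and the statistics layer used in imaging-biomarker studies
    of lymphovascular invasion in non-small cell lung cancer: intraclass
    correlation with qualitative bands, normality-routed group comparison,
    ROC analysis with Youden cutoffs and DeLong confidence intervals and
    tests, and univariate-to-multivariate logistic biomarker combination.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    withr,
    minpack.lm,
    RNifti,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    dplyr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
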