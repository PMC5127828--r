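Package: qeeglda
Title: Spectral Parameterization and Regularized LDA Discrimination of
    Clinical EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative-EEG pipeline for discriminating dementia groups
    (healthy controls, Alzheimer's disease, vascular dementia) from
    resting-state multi-channel EEG. Provides a synthetic cohort generator
    with known ground-truth spectral parameters, Welch-style average power
    spectra with amplitude/power/spatial-deviation artifact rejection, a
    six-parameter spectral model (aperiodic 1/f component plus Gaussian
    alpha peak plus baseline) fitted per channel, Box-Cox feature
    normalization with within-fold correlation screening, a binary linear
    discriminant with analytic (Ledoit-Wolf) covariance shrinkage, and
    repeated stratified 10-fold cross-validation with ROC/AUC summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    signal,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    MASS,
    pROC,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
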