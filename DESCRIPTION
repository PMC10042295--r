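Package: ecg2img
Title: ECG Waveform-to-Image Encoding and Short-Term Prognosis Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts 10-second multi-lead electrocardiogram waveforms into
    stacked-lead grayscale images (augmented-lead derivation, three-way
    segmentation, polyline rendering with linear interpolation, Lanczos
    reduction, 224x224 8-bit PNG output) and evaluates short-term mortality
    classifiers on them: a backbone-agnostic transfer-learning harness with a
    built-in small 2-D convolutional network and a four-branch 1-D baseline,
    patient-level score aggregation, survivor undersampling, ten-fold
    train/validation/test cross-validation, confusion metrics with ROC/AUC,
    and GradCAM attribution overlays. A synthetic labelled ECG cohort
    generator with class-dependent morphology (ST-segment offset, rhythm
    irregularity, R-wave height) exercises the whole pipeline without
    clinical data. Waveform I/O covers a lead-per-column CSV interchange and
    a documented minimal MFER-style tag-length-value binary subset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
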