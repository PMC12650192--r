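Package: breathfit
Title: Breathing-Cycle Segmentation and Respirator-Fit Classification from
    Intra-Mask Sensor Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting the fit of tight-fitting industrial
    respirators from intra-mask pressure, temperature and relative-humidity
    time series sampled at 10 Hz. Provides a physics-informed generator of
    labeled synthetic intra-mask recordings (cycle-synchronous pressure
    oscillations, exhalation-driven microclimate dynamics, leak-induced
    attenuation and decorrelation), Butterworth bandpass and z-score
    preprocessing, temperature-anchored peak-valley-peak breathing-cycle
    segmentation with a fixed-length sliding-window alternative, a
    22-feature per-cycle schema, and classifier evaluation (random forest,
    RBF support vector machine, gradient-boosted trees) under stratified
    k-fold and leave-one-subject-out cross-validation with SMOTE class
    balancing applied to training folds only.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    e1071,
    ranger,
    xgboost,
    pROC,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
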