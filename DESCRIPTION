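Package: fbcfuse
Title: Hybrid EEG-fNIRS Mental Workload Analysis with Functional
    Connectivity Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for multi-level mental workload (n-back)
    classification from simultaneous EEG and fNIRS recordings. Provides a
    seeded synthetic-session generator with planted workload effects,
    zero-phase Butterworth preprocessing, modified Beer-Lambert conversion,
    band power spectral features, four functional brain connectivity
    estimators (Pearson correlation, magnitude-squared coherence,
    histogram mutual information, phase-locking value), ANOVA-ranked
    feature selection with multimodal fusion, SVM cross-validated
    classification with ROC/AUC reporting, sliding-window sensitivity
    sweeps, and topographic/connectivity visualisation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    e1071,
    jsonlite,
    class,
    MASS,
    rpart,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
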