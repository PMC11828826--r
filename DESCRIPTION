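Package: vmdeeg
Title: Variational Mode Decomposition Band-Power Features for EEG Emotion Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end pipeline for frequency-domain analysis of evoked-emotion
    EEG recordings. Provides a labelled synthetic-EEG generator emulating a
    visual-stimulus paradigm (happy/sad/fear blocks with relaxation intervals),
    a three-step preprocessing chain (zero-phase FIR bandpass, Savitzky-Golay
    trend subtraction, ICA-based ocular artifact removal), a from-scratch
    variational mode decomposition (VMD) solver with a compiled ADMM kernel,
    sliding-window band-power feature extraction over five canonical EEG bands
    and five intrinsic mode functions, multi-classifier evaluation (KNN, SVM,
    decision tree, random forest) with stratified cross-validation, per-IMF and
    per-band ablation tables, and feature-importance reports. Recordings can be
    written and read as CSV or 16-bit EDF with an events sidecar.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    e1071,
    jsonlite,
    randomForest,
    rpart,
    signal,
    stats,
    tools,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
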