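Package: errpdecode
Title: Transferable Ensemble Decoding of Error-Related Potentials from EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A cross-subject ("transferable") pipeline for single-trial
    detection of error-related potentials (ErrP) in the feedback period of a
    P300-speller task. Provides a synthetic multichannel EEG generator that
    emulates the speller session structure (feedback-locked ErrP waveforms,
    pink-noise background, alpha rhythm, blink artifacts), causal elliptic
    band-pass filtering, ICA-based ocular artifact removal, Savitzky-Golay
    smoothing, feedback-locked epoching with baseline correction and
    bin-mean downsampling, greedy backward electrode elimination driven by
    cross-validated AUC, a posterior-averaging ensemble of LDA, regularized
    QDA and L1/L2 logistic regression, a pseudo-online streaming decoder,
    and evaluation utilities (accuracy, F1, ROC-AUC, classifier rank tables
    and the Friedman statistic).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    glmnet,
    jsonlite,
    Rcpp,
    signal,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    MASS,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
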