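Package: mieeg
Title: Motor-Imagery EEG Classification with Multiscale PCA Denoising,
    Wavelet-Packet Features and Ensemble Learners
Version: 0.1.0
Authors@R:
    person("mieeg", "developers", email = "mieeg-dev@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for two-class motor-imagery (MI)
    electroencephalogram (EEG) classification. Multichannel trial
    segments are denoised by multiscale principal component analysis
    (per-scale PCA across channels on Daubechies wavelet coefficients),
    decomposed into 16 subbands by a 4-level wavelet packet transform,
    summarised into a 95-dimensional statistical feature vector, and
    classified by Rotation Forest or Random Subspace ensembles over six
    base learners (SVM, k-NN, random forest, entropy decision trees).
    Includes a synthetic generator of two-class oscillatory EEG with
    event-related desynchronization structure, stratified k-fold
    cross-validated evaluation (accuracy, F-measure, AUC), EDF and
    delimited-text I/O, and a command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    data.table,
    jsonlite,
    quadprog,
    FNN,
    optparse,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
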