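Package: gradentropy
Title: Certainty Scoring and Entropy-Based Heatmap Evaluation for 1D
    Convolutional Signal Classifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for asking whether a 1D convolutional network classifying
    short electrophysiology signals (e.g. one-second intracranial EEG epochs)
    is confident for the right reasons. Provides a per-prediction certainty
    index computed from pre-softmax (logit) outputs, signed one-dimensional
    Grad-CAM relevance heatmaps taken from the last convolutional layer,
    sliding-window sample-entropy series as a model-free measure of local
    signal information content, zero-padded lagged cross-correlation between
    heatmaps and signals or entropy series, and simple regression summaries of
    maximal correlation against certainty. Includes a compact trainable 1D CNN
    with k-fold cross-validation, a two-class synthetic signal generator with
    localized high-frequency bursts, and an orchestrator that sweeps the
    sample-entropy parameter grid.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    signal,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
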