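Package: mammofuse
Title: Bottleneck-Residual Deep Features, Kernel-CCA Fusion and Quantum
    GNDO Selection for Mammogram Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An end-to-end, desk-scale pipeline for two-class (benign versus
    malignant) mammogram mass classification. Implements two bespoke
    bottleneck-residual convolutional neural networks (a parallel-branch
    three-block model and a single-path four-block model) with global
    average pooling feature extraction and Grad-CAM lesion localization;
    Gaussian-kernel canonical correlation analysis with entropy-based
    feature weighting for fusing the two 2,048-dimensional deep feature
    sets; a quantum-behaved generalized normal distribution optimizer
    (Q-GNDO) used as a wrapper feature selector; five shallow neural-network
    classifier presets with stratified cross-validation and a full
    confusion-matrix metric suite; and a paired Student's t analysis of
    classifier accuracies. A seedable synthetic-data module emulates
    lesion-bearing mammograms, correlated feature pairs with a planted
    canonical correlation, and feature-selection benchmarks with known
    informative columns, so every stage is testable without restricted
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    png,
    yaml,
    jsonlite,
    pROC,
    lhs
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
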