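Package: splsnest
Title: Sparse PLS-DA with Nested Leave-One-Out Model Selection for
    Metabolite Feature Tables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits sparse partial least squares discriminant analysis
    (sPLS-DA) models to sample-by-feature metabolite abundance tables and
    selects the number of retained variables (nkeep) and latent components
    (ncomp) by a nested double leave-one-out cross-validation: an outer loop
    filters features by variable importance in projection (VIP), an inner
    loop tunes the component count by mean squared error of prediction
    (MSEP), and the outer-test MSEP grid is rank-transformed and smoothed
    with a 3x3 convolution kernel before the optimum is chosen.  Includes
    preprocessing (log transform, centring, unit-variance scaling, PCA-based
    outlier screening), mean-VIP relevance aggregation across outer folds,
    confirmatory Kruskal-Wallis and Wilcoxon-Mann-Whitney tests with exact
    small-sample modes, two-way hierarchical clustering, an end-to-end
    pipeline driver, and a synthetic log-normal feature-table generator with
    planted class-discriminative effects.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
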