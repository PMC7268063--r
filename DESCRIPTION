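Package: stableconn
Title: Bootstrap-Stable Feature Selection for Connectome-Based Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Stability-filtered feature selection for predicting continuous
    phenotypes from functional-connectome edge weights. Every edge is screened
    by Spearman correlation against the trait inside bootstrap resamples drawn
    with or without replacement, and only edges that reach significance in at
    least a frequency-percentage threshold of resamples are retained. The
    surviving positive, negative and combined edge sets feed connectome-based
    predictive modelling (CPM), linear support vector regression, LASSO and
    ridge regression inside a sorted round-robin nested cross-validation with
    grid search over the resampling parameters. A synthetic connectome
    generator with planted signal edges and optional contamination makes the
    full pipeline testable without access to restricted imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    glmnet,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    e1071,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
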