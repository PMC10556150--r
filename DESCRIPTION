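Package: dfncstates
Title: Dynamic Functional Network Connectivity States from Component Time Courses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sliding-window dynamic functional network connectivity (dFNC) analysis
    for resting-state fMRI component time courses. Estimates per-window connectivity
    with an L1-regularised inverse covariance (graphical lasso), clusters windowed
    connectivity into recurring brain states with Manhattan-distance k-means
    (coordinate-wise-median centroids), computes temporal state metrics (mean dwell
    time, fraction of time, number of transitions), and provides the downstream
    statistical layer: two-sample t-tests (from raw data or printed summary
    statistics), Levene variance checks, Pearson correlations with
    Benjamini-Hochberg FDR control, bias-corrected and accelerated (BCa) bootstrap
    mediation, and centroid-regression feature extraction with linear support
    vector machine classification. Includes a hidden-Markov synthetic-cohort
    generator so every stage is testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    signal,
    e1071,
    pROC,
    cluster,
    jsonlite,
    withr
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    car,
    MASS,
    knitr
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
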