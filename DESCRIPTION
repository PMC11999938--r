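Package: emgforce
Title: Muscle Force Estimation from High-Density Surface EMG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates exerted muscle force from high-density surface
    electromyography (HD-sEMG) grids. Implements a full processing chain:
    channel quality screening, FIR band-pass filtering, PCA spatial
    filtering, envelope extraction, non-negative matrix factorization
    (NMF) based optimal-channel selection, and sliding-window sample
    segmentation; a stacked-LSTM sequence regressor trained with an RMSE
    loss; layer-freezing transfer-learning calibration of a source
    network into gesture-specific target networks; and a deviation-score
    assessment of abnormal EMG-force relationships with rank-based group
    comparisons (Mann-Whitney U, Kruskal-Wallis, Dunn-Bonferroni,
    Friedman). Includes a synthetic HD-sEMG/force simulator with
    configurable force modes, spatial activation maps, channel faults and
    pathology models so the whole pipeline is testable without clinical
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
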