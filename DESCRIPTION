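Package: fcdyn
Title: Dynamic Directed Functional Connectivity from Multichannel
    Intracranial Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Ensemble estimation of directed functional connectivity from
    multichannel electrophysiology (SEEG-like) time series: pairwise and
    lagged correlation, multivariate autoregressive (MVAR) spectral
    coherence and partial directed coherence, fused by tunable fuzzy
    membership functions whose parameters are optimized by a genetic
    algorithm against simulated ground-truth networks. Sliding-window
    connectivity dynamics (FCD), unsupervised task-state clustering
    (spectral, BIRCH, t-SNE), supervised task identification with
    stratified time-separated cross-validation, region-level centrality
    profiles (degree, closeness, betweenness, Katz), and between-task
    link and degree comparisons (Wasserstein distance, Mann-Whitney U).
    Includes a stable-MVAR synthetic session generator with known
    ground-truth networks for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    igraph,
    randomForest,
    e1071,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
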