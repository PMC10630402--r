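Package: socialcpm
Title: Connectome-Based Predictive Modeling of Social Attention with
    Bootstrap Exploratory Graph Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for predicting individual differences in behavior from
    task-based functional connectivity. Implements connectome-based
    predictive modeling (CPM) with cross-validated edge selection,
    confound residualization, network-strength linear models, permutation
    significance testing, robust-edge masks and anatomical (lobewise)
    summaries; signal-detection scoring of one-back task performance with
    log-linear-corrected d-prime; construction of Fisher-z Pearson
    connectivity matrices from node timecourses; and bootstrap exploratory
    graph analysis (graphical-lasso partial-correlation networks, Louvain
    communities, item stability, standardized network scores) for
    questionnaire data. A synthetic-data generator with planted signal
    provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    MASS,
    Matrix,
    igraph,
    clue,
    jsonlite,
    yaml,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
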