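Package: symptomnet
Title: Regularized Partial-Correlation Networks for Ordinal Symptom Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimation, description and comparison of psychometric symptom
    networks from ordinal questionnaire data. Fits sparse Gaussian graphical
    models by graphical lasso over a penalty path with extended Bayesian
    information criterion (EBIC) selection, computes node centrality
    (strength, expected influence, harmonic closeness, betweenness),
    nodewise predictability, and flow decompositions around a focal node,
    quantifies edge accuracy and centrality stability by nonparametric and
    case-dropping bootstraps (correlation stability coefficient), and
    compares two groups with a permutation network comparison test on
    global strength and network structure. A latent-Gaussian threshold
    simulator generates ordinal item data with known network structure and
    controllable between-group edge-weight differences.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    yaml,
    MASS,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
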