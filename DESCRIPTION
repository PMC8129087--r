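Package: traitmk
Title: Constrained and Hidden-Rate Markov Models for Discrete Trait
    Evolution on Phylogenies
Version: 1.0.0
Authors@R: person("Trait", "Markov Maintainers",
    email = "maintainers@traitmk.org", role = c("aut", "cre"))
Description: Maximum-likelihood inference of discrete binary trait
    evolution on rooted, time-calibrated phylogenies. Supports equal-rates
    (ER) and all-rates-different (ARD) Mk models, hidden rate-category
    (hidden Markov) extensions with one or two rate regimes, joint models
    of two correlated binary traits with constrained transition matrices,
    node state clamps for hypothesis tests (e.g. enforcing independent
    trait origins), AICc model comparison with Akaike weights, marginal
    ancestral state reconstruction, and transition counting. Includes a
    synthetic-data module (pure-birth trees, Gillespie trait histories
    with recorded ground truth) and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    jsonlite,
    optparse,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    Matrix,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
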