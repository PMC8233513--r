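Package: clockshift
Title: Local-Clock Rate Acceleration Tests for Noncoding Regulatory Regions
Version: 0.1.0
Authors@R:
    person("clockshift", "developers", email = "clockshift@example.org",
           role = c("aut", "cre"))
Description: Maximum-likelihood tools for detecting lineage-specific rate
    shifts in noncoding regions against an intron reference. Implements
    Felsenstein pruning under HKY with discrete-gamma rate variation, local
    molecular clock models with labelled branch rate classes, the M0 codon
    model for dN/dS estimation, delta-method tests for focal-branch rate
    acceleration, marginal ancestral sequence reconstruction, Fitch parsimony
    for discrete trait changes, and phylogenetic logistic regression of binary
    expression states on life-history covariates. Ships seeded sequence and
    trait simulators so every analysis can be exercised end-to-end on
    synthetic data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    Matrix,
    numDeriv,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
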