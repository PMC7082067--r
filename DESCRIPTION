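Package: imtracer
Title: Time-Dependent Isolation-Migration Inference from Pairwise Coalescence Rates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Fits a two-island isolation-migration model with time-dependent
    population sizes and a time-dependent symmetric migration rate to
    piecewise-constant pairwise coalescence rate estimates, yielding migration
    rate profiles m(t), cumulative migration probabilities M(t) and summaries
    of deep ancestry. Includes an exact structured-coalescent rate engine for
    demographic scenarios (splits, pulse admixture, continuous migration,
    bottlenecks), a pairwise SMC' hidden Markov model rate estimator with
    expectation-maximization over piecewise-constant coalescence rates,
    readers and writers for the rate-table and multihetsep formats, sequence
    simulation backed by msprime, block bootstrap resampling and switch-error
    injection for robustness studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
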