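Package: perishift
Title: Paleobiome-Informed Models of Biome Shifts and Discrete Trait
    Evolution on Time-Calibrated Phylogenies
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Continuous-time Markov chain (CTMC) models of discrete
    character and biome-by-region evolution on time-calibrated phylogenies
    (chronograms).  Provides epoch-stratified rate matrices informed by
    paleogeographic adjacency and paleobiome availability, Felsenstein
    pruning likelihoods with per-node rescaling, marginal and
    model-averaged ancestral state estimation, stochastic character
    mapping (rejection sampling with a uniformization fallback),
    reversible-jump MCMC over zero/nonzero transition-rate models with
    indicator-based Bayes factors, a maximum-likelihood test of correlated
    evolution between binary characters, and a synthetic-data generator
    (birth-death chronograms and forward Gillespie character simulation)
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    phytools,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
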