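Package: spclone
Title: Single-Progenitor Clone Dynamics: Simulation and Inference for
    Lineage-Tracing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stochastic modelling and parameter inference for the
    single-progenitor (SP) model of squamous epithelial tissue
    maintenance. Provides exact clone-size probability distributions via
    the branching-process generating function, a truncated
    master-equation integrator, Markovian (Gillespie) and non-Markovian
    (gamma cell-cycle) clone simulators, grid-search maximum-likelihood
    estimation of the symmetric-division probability r and progenitor
    fraction rho, sequential Monte Carlo approximate Bayesian
    computation with a summed Kolmogorov-Smirnov distance, and a
    synthetic lineage-tracing cohort generator with inter-mouse
    biological variation for method validation and experimental design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
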