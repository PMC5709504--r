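Package: multistage
Title: Multi-Stage Markov Models of the Cell Cycle for Exact Stochastic
    Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Represents cell-cycle time as a chain of exponentially
    distributed stages, so that Erlang and exponentially modified Erlang
    cell-cycle-time distributions can be simulated exactly with the
    Gillespie stochastic simulation algorithm. Provides the
    hypoexponential family of densities, moments and exact stage-wise
    samplers; the analytic mean dynamics of the stage-structured
    pure-birth chain (complex root-of-unity series solutions, asymptotic
    growth law, steady-state stage proportions and their infinite-stage
    limits); a compiled exact Gillespie engine for stage chains and
    division processes with fate choice; a cancer stem-cell
    proliferation/differentiation model; a two-dimensional lattice
    volume-exclusion growth-to-confluence model with two division-abort
    rules; and least-squares fitting of exponential, Erlang and
    exponentially modified Erlang densities to binned cell-cycle-time
    histograms, with a synthetic histogram generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
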