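Package: maxcalnet
Title: Network Inference from Dynamical Node Signals by Maximum Caliber
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Infers time-lagged node-node couplings and per-node biases from
    ensembles of discrete-time activity trajectories using the principle of
    Maximum Caliber, the dynamical analogue of maximum entropy.  Provides an
    exact brute-force solver for small binary systems, two scalable
    approximations (a factorized 'Uncoupled' solver and a 'Linear Coupling'
    scheme based on linear-response inversion of the trajectory covariance
    matrix), an exactly solvable two-agent Gaussian system with a guaranteed
    error bound, and two worked model systems: a bistable genetic toggle
    switch with closed-form critical point, and a synthetic 40-neuron dynamic
    Ising network sampled by space-time Metropolis Monte Carlo.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
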