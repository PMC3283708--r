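Package: RyRgate
Title: Kinetic Modelling and Single-Channel Analysis of RyR2 Gating Under
    FKBP12/FKBP12.6 Regulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for modelling the gating of the cardiac ryanodine receptor
    (RyR2) under dual regulation by the FK-binding proteins FKBP12 (a
    high-affinity partial agonist) and FKBP12.6 (a high-affinity,
    near-zero-efficacy competitor). Provides the five-state FKBP-occupancy
    scheme with its closed-form mass-action equilibrium and
    occupancy-dependent opening-rate law; exact continuous-time Markov chain
    (Gillespie) simulation of the joint occupancy-by-gating process under
    piecewise-constant ligand protocols; concentration-response and EC50
    estimation; a synthetic single-channel recording generator (two-level
    current, Gaussian low-pass filtering, additive noise, modal gating); and
    the standard single-channel analysis chain: 50%-threshold idealization,
    windowed open probability, dwell-time extraction with short-event
    exclusion, and maximum-likelihood exponential-mixture fitting with
    component-count selection.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    yaml,
    jsonlite,
    minpack.lm
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
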