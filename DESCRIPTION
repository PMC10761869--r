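Package: burstdyn
Title: Diffusion-Based smFRET Burst Analysis, Photon-by-Photon Hidden
    Markov Modelling, and Chaperone Chase Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of microsecond alternating-laser-excitation (us-ALEX)
    single-molecule FRET photon streams: background estimation by censored
    interphoton-delay fitting, sliding-window and dual-channel burst search,
    uncorrected apparent FRET efficiency (E*) and stoichiometry (S), burst
    variance analysis against the binomial shot-noise static limit, and
    multi-parameter photon-by-photon hidden Markov modelling with
    arrival-time-dependent transition operators, integrated-complete-likelihood
    model selection, Viterbi dwell analysis, and closing-equilibrium
    estimation with subset-based uncertainties.  Includes a continuous-time
    Markov photon-stream simulator for two-state conformational exchange with
    acceptor blinking and contaminating single-dye species, and mass-action
    models of substrate handover (chase) kinetics with exponential and
    hyperbolic fits.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    minpack.lm,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
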