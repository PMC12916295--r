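Package: nmdadcm
Title: Conductance-Based Dynamic Causal Modelling of NMDA Channel Blockade
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for inferring voltage-dependent NMDA-receptor channel
    blockade from evoked electrophysiological responses. Implements a
    two-region conductance-based canonical microcircuit neural mass model
    with a voltage-sensitive magnesium switch whose steepness is scaled by a
    log-latent blockade parameter, a forward model projecting source
    depolarisation to windowed sensor modes, variational Laplace model
    inversion (Gauss-Newton with Levenberg-Marquardt damping and
    closed-form noise-precision updates), Parametric Empirical Bayes for
    second-level inference of drug, severity and session effects with
    Bayesian model reduction and averaging, sensor-level mismatch-negativity
    statistics, and a synthetic cohort generator emulating a
    placebo-controlled crossover study and a longitudinal patient cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
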