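Package: axogain
Title: Dynamic Gain Analysis of Ball-and-Stick Neuron Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for studying ultrafast population
    coding in a two-compartment-class (ball-and-stick) neuron model. Provides a
    backward-Euler cable-equation integrator with a point sodium conductance at
    the axon initial segment, Ornstein-Uhlenbeck stimulus synthesis, operating
    point calibration to prescribed firing rate and inter-spike-interval
    variability, spike-triggered-average estimation of the dynamic gain function
    with cyclic-shift significance thresholds and bootstrap confidence
    intervals, steady-state bifurcation analysis of axo-somatic voltage
    decoupling under somatic voltage clamp, passive transfer impedance, and
    action-potential phase-plane tools.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
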