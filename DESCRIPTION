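Package: cardioloop
Title: Closed-Loop 0D Cardiovascular Modelling and Decomposed Inverse Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Lumped-parameter (0D) closed-loop model of the human circulation
    built from three- and two-element windkessel compartments, dynamic
    Bernoulli valve models with effective-orifice-area interpolation, and
    active-stress-driven pressure-volume chamber surrogates, integrated
    implicitly with a One-Step-theta scheme and a monolithic Newton solver.
    Provides a decomposed inverse-analysis framework that identifies
    patient-specific parameters from pressure, flow and chamber-volume time
    series: arterial windkessel fits on a flow-driven pressure ODE, valve
    effective-orifice-area fits from transvalvular pressure and flow,
    venous dependency rules, and an adjoint-gradient L-BFGS calibration of
    per-chamber active-stress parameters gated by a cycle-periodicity
    criterion. Includes synthetic scenario generation emulating a repaired
    tetralogy-of-Fallot state with severe pulmonary regurgitation,
    measurement synthesis at clinical sampling rates, end-to-end twin
    experiments, and in-silico pulmonary valve replacement with
    pre/post-operative outcome tables.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    graphics,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
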