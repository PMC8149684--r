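Package: cardiolpm
Title: Doppler-Based Lumped-Parameter Modelling of the Left Heart and
    Circulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Patient-specific lumped-parameter (0-D) simulation of the left
    heart and systemic/pulmonary circulation driven entirely by non-invasive
    Doppler-echocardiography and cuff-pressure measurements.  Implements
    double-Hill time-varying elastance chambers, net-pressure-gradient valve
    elements with energy-loss coefficients, a closed circuit of windkessel
    compartments integrated to periodic steady state, and the two-stage
    response optimization that fits pulmonary inflow to the forward LVOT
    stroke volume and the systemic resistance/compliances to brachial
    systolic and diastolic pressures.  Also provides global and local
    hemodynamic metrics (ejection fraction, stroke work, systemic arterial
    compliance, E/A ratio, transvalvular gradients, TAWSS, vortex sphericity
    index), pointwise St. Venant-Kirchhoff tissue kernels with Robin
    pressure-boundary coefficients and a spherical-shell Young's-modulus
    calibration, plus a deterministic synthetic-patient generator for
    parameter-recovery experiments.
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
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
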