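Package: armbalance
Title: Arm-Strategy Balance Recovery Simulation via Nonlinear Model
    Predictive Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates sagittal-plane balance recovery during quiet standing
    with a three-joint, five-link rigid-body model of the human body (foot,
    lower body, upper body and a lumped pair of arms) actuated at the ankle,
    hip and shoulder.  A constrained nonlinear model-predictive controller
    stabilises the model against horizontal pushes applied at the upper-body
    centre of mass, under joint-angle and joint-torque box constraints, for
    three arm conditions (active, passive, fixed).  Provides closed-loop
    simulation, balance metrics (RMS deviation, mechanical energy
    consumption, joint correlations, phase portraits), force-sweep and
    ankle-capacity experiment drivers, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
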