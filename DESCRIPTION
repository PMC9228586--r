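Package: bbrmotor
Title: Deterministic Simulation of Polyvalent Burnt-Bridge Ratchet Motors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a polyvalent molecular motor hub that moves along a
    one-dimensional track by a burnt-bridge ratchet mechanism.  The hub binds
    surface-tethered substrate through many simultaneous elastic linkages,
    catalytically destroys ("burns") bound substrate, and is propelled by the
    asymmetric substrate landscape its own consumption creates.  The package
    integrates the coupled deterministic dynamics of the hub position and two
    substrate concentration fields (surface-bound and hub-bound complex) by
    the method of lines with adaptive Runge-Kutta stepping, supports
    force-dependent (Bell-like) complex unbinding, extracts steady-state
    velocity and substrate consumption rate, computes the Stokes efficiency,
    converts between physical and dimensionless parameterizations, and runs
    parameter sweeps over the dimensionless control parameters (burn rate,
    substrate concentration, substrate turnover, and unbinding kinetics).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
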