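Package: phikin
Title: Phi-Order Kinetics of Bimolecular Photoreactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Kinetic modelling of bimolecular photoreactions under continuous
    monochromatic irradiation. Implements the Phi-order integrated rate laws
    (a decadic logarithm bearing an exponential) for the reaction topologies
    that admit closed-form integration, a classical fourth-order Runge-Kutta
    integrator for those that do not, and the associated quantification
    machinery: overall and thermal bimolecular rate constants, quantum
    yields from fitted initial rates, and photonic yields. Includes
    nonlinear least-squares fitting of kinetic traces, comparison against
    the classical first-, second- and zeroth-order models, a synthetic-data
    generator with seeded measurement noise, an audit of the validity
    conditions of the solvable cases, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
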