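Package: fermpump
Title: Fermentation Kinetics Models for Yeast-Powered Passive Micropumps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the CO2 production dynamics of yeast-fermentation-driven
    passive micropumps. Implements a three-phase (startup, stable, decline)
    production-rate model in six- and four-parameter forms, bounded nonlinear
    least-squares fitting of the model to measured rate or volume traces,
    closed-form and numeric peak-performance analytics, an affine layer
    mapping pump configuration (yeast inoculum mass, sucrose concentration)
    to model parameters with coefficient refitting and inverse design,
    kymograph displacement-trace processing with Hagen-Poiseuille pressure
    requirements, and a seeded synthetic-trace generator for testing the
    full pipeline without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    pracma,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
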