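Package: chainheat
Title: Dipolar Chain Self-Assembly and Hyperthermia Heating of Magnetic Nanoparticles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the field-driven self-assembly of magnetite nanoparticles
    into linear chains and the consequences for magnetic particle hyperthermia.
    Provides an on-the-fly coarse-grained Brownian dynamics simulator with
    slender-body anisotropic chain diffusion and dipolar attraction zones, a
    finite-temperature Stoner-Wohlfarth hysteresis-loss model predicting
    specific loss power (SLP) for random versus field-aligned configurations,
    lumped and one-dimensional radial heat-transfer models producing
    heating/cooling temperature traces, and initial-slope SLP extraction from
    calorimetric traces. A synthetic-data module generates particle
    populations, simulation configurations and noisy temperature traces so the
    whole pipeline is testable without measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
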