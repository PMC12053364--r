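Package: rootkrs
Title: Root System Architecture Simulation and Whole-Root-System Hydraulic
    Conductance Analysis for Wheat
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools linking wheat root system architecture to whole-root-system
    hydraulic conductance (Krs). Provides a stochastic simulator of winter wheat
    root development (seminal, crown and lateral roots with tiller-linked crown
    emergence), an exact transmission-line solver for the hydraulic conductance
    of a root network with age-dependent radial and axial conductivities
    (verified against a discretized resistor-network oracle), a pressure-chamber
    Jv(P) estimation chain with linearity quality control and IQR/Grubbs outlier
    screening, breeding-trend statistics on log-transformed traits (mixed models
    with a season random intercept, back-transformed percent change per century),
    and a synthetic-data generator reproducing the statistical structure of
    shovelomics trait tables and pressure-chamber sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    nlme,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
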