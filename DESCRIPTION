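Package: lovfret
Title: Kinetic Analysis of LOV2 Optogenetic Actuators Read Out by
    Resonance Energy Transfer
Version: 0.1.0
Authors@R:
    person("lovfret", "maintainers", email = "lovfret@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying the photocycle of LOV2-based
    optogenetic actuators from fluorescence quench/dequench traces.
    Implements the first-order reversible two-state switching model
    (dark LOV-445 versus cysteine-adduct LOV-390), closed-form trace
    equations for donor dequench and acceptor quench cycles,
    shared-parameter global nonlinear least-squares fitting with
    standard errors and derived quantities (sensitivity, dark
    relaxation time constant, transfer limit, ED50), an adduct-state
    simulator for designing minimal-light illumination trains,
    nucleocytoplasmic translocation and kinase-translocation-reporter
    dose-response analyses, photon-flux unit conversions, Forster
    distance arithmetic, and seeded synthetic-data generators that
    emulate the plate and imaging protocols so the whole pipeline is
    testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
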