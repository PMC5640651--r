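Package: bindkin
Title: Label-Free Biosensor Binding Kinetics: Simulation, Fitting and
    Inference for 1:1 Interaction Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing label-free optical biosensor (resonant
    mirror / surface plasmon resonance) binding experiments under a
    pseudo-first-order 1:1 interaction model. Simulates association and
    dissociation sensorgrams with realistic instrument noise, fits mono-
    and bi-exponential models with nested F-test model selection, infers
    association and dissociation rate constants from the observed-rate
    versus concentration regression, estimates the equilibrium
    dissociation constant by both the kinetic-ratio and binding-isotherm
    routes with first-order error propagation, converts immobilisation
    responses to surface densities and molar concentrations for
    stoichiometry estimates, compares kinetic parameters across buffer
    conditions and ligand variants, and simulates two-ligand one-site
    competitive pre-saturation assays.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
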