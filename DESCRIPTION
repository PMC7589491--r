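Package: franzpampa
Title: Apparent Permeability Estimation for Franz-Cell PAMPA Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for parallel artificial membrane permeability
    assays (PAMPA) run on Franz vertical diffusion cells. Estimates apparent
    permeability (Papp) from receiver-compartment concentration-time data
    under sink conditions (steady-state flux through the best-fitting linear
    window, with sampling-replacement dilution correction) and without the
    sink assumption (a two-compartment recursive model fitted by residual
    minimisation). Includes a mass-conserving Franz-cell simulator with known
    ground-truth permeability, BCS permeability classification against a
    metoprolol internal reference, dose-number calculation, and in vitro-in
    vivo correlation of Papp against human fraction absorbed, with a packaged
    reference table of BCS model drugs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
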