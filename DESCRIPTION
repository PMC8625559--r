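Package: skinflux
Title: In Vitro Skin Permeation Analysis for PAMPA and Franz-Cell Assays
Version: 0.1.0
Authors@R:
    person("skinflux", "maintainers", email = "maintainers@skinflux.dev",
           role = c("aut", "cre"))
Description: Tools for analysing in vitro permeation experiments on
    artificial membranes (Skin-PAMPA) and ex vivo skin mounted in
    diffusion cells. Converts raw plate absorbances to
    replacement-corrected cumulative permeated amounts, estimates
    steady-state flux, lag time, permeability coefficients and
    normalised AUC, applies sink-condition and donor-depletion quality
    checks, implements stepwise approximate solubility classification
    and shake-flask logP, compares artificial-membrane screens against
    ex vivo skin kinetics, and ships a Fickian membrane-diffusion
    simulator so every pipeline stage is testable without wet-lab data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
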