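Package: phenolkin
Title: Kinetic, Mass-Transfer and Thermodynamic Modelling of Phenolic Extraction Curves
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Models solid-liquid extraction time courses of phenolic compounds,
    as measured for ultrasound-assisted and conventional shaking extraction.
    Fits pseudo-second-order kinetics with Arrhenius temperature dependence,
    estimates effective diffusivity from Crank's series solution of Fick's
    second law in a sphere with residual-resampling bootstrap confidence
    intervals, derives external mass-transfer coefficients and Biot-number
    diagnostics, and computes Van't Hoff / Gibbs thermodynamic parameters.
    Includes assay calibration helpers (Folin-Ciocalteu, aluminium chloride,
    DPPH), a seeded synthetic-data generator for end-to-end validation, and a
    pipeline that assembles publication-style report tables.
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
    withr,
    optparse
Config/testthat/edition: 3
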