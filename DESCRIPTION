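Package: combindex
Title: Median-Effect Dose-Response and Drug-Combination Synergy Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying two-drug interactions from cell-viability
    assays using the mass-action median-effect model. Converts raw MTT
    absorbances to percent viability, fits median-effect parameters (Dm, m)
    by log-linearisation, and computes the Chou-Talalay combination index,
    dose-reduction index, isobologram coordinates and curve-shift overlays
    for constant-ratio and checkerboard combination designs. Also provides
    time-resolved IC50 estimation and kinetic-shape classification for
    impedance-based (cell index) cytotoxicity traces, and a synthetic-data
    generator with planted ground truth (per-drug potency and slope, Loewe
    interaction level, noise, seed) so that every analysis stage can be
    validated without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
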