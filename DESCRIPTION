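Package: dialsim
Title: Dialyzer Mass-Transfer and Compartment Kinetics for Antibiotic-Enriched Dialysate
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates diffusive drug transport across a countercurrent
    hemodialysis filter during continuous veno-venous hemodialysis (CVVHD),
    with a well-mixed single-compartment circuit, a Beer-Lambert
    spectrophotometric assay layer, least-squares calibration of the dialyzer
    mass-transfer coefficient (K0A) from per-pass extraction data, and a
    seeded synthetic-experiment generator emulating a bench circuit with
    antibiotic-enriched dialysate (meropenem 0/16/64 mg/L over a 3x3 grid of
    blood and dialysate flows).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    Matrix,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
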