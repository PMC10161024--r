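Package: vesselperm
Title: Permeability and Barrier-Function Analysis for Microvessel-on-Chip
    Leakage Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies vascular barrier function in 3D microvessel-on-chip
    assays from time-lapse fluorescence images of tracer leakage. A
    mass-transport estimator converts the growth rate of extraluminal
    fluorescence into an apparent permeability coefficient (m/s) with
    adaptive fitting windows, and reports the barrier-function index
    -log10(P) and its change relative to iso-osmotic controls. Includes a
    physics-based synthetic-data generator (radial diffusion across a
    semipermeable cylindrical membrane, projection imaging with shot and
    read noise) so the whole pipeline is testable against known ground
    truth, plus colocalized-pixel-fraction analysis, label-mask cell
    morphometry, and scalar plate-assay normalizations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    Matrix,
    jsonlite,
    stats,
    graphics,
    grDevices,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
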