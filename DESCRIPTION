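Package: tevarsim
Title: Desk-Scale Finite-Element Simulation of Thoracic Stent-Graft Mechanics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Explicit-dynamics structural simulation of self-expanding
    Nitinol stent-grafts at desk scale: superelastic shape-memory-alloy
    ring mechanics with fibre-integrated corotational beams, zero-compression
    fabric membranes for the graft, penalty contact with rigid crimpers,
    catheters and vessels, crimp/release radial-force tests, stent
    pre-stress, tracking and virtual-catheter deployment protocols,
    Nitinol parameter calibration against force-diameter curves, and
    spline-based opening-area validation metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
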