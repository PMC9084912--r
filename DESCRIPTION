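Package: podcpm
Title: Pseudopod-Driven Cellular Potts Simulation and Cell-Track Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A 2D Cellular Potts Model engine with a pluggable energy-term
    stack for simulating cell migration: base adhesion and elastic area
    constraints, a basic target-direction persistence extension, the Act
    actin-memory extension, an explicit pseudopod finite-state machine, and
    pseudopod tip-adhesion, pulling-force and touch-behavior extensions that
    together reproduce density-dependent increases in cell speed and
    persistence. Includes the matching cell-track quantification suite
    (instantaneous speed, directional autocorrelation with exponential
    persistence fit, streaming-angle analysis with drift correction, Ripley L
    spatial statistics, confinement ratio, Fisher-averaged correlograms) and
    seeded fixture generators with analytic ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    minpack.lm,
    spatial,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    tiff
Config/testthat/edition: 3
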