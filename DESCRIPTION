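Package: zoneperm
Title: Permutation Tests for the Areal Extent of No-Data Zones in
    Bivariate Scatterplots
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Scatterplots of biological data often have corner regions
    that contain no observations ("no-data zones"), suggesting constraint
    or promotion of the dependent variable.  zoneperm delineates such a
    zone with a boundary line built from the scatter's Pareto-extreme
    points, measures the zone's areal extent Q relative to the data
    bounding box, and assesses its significance with a permutation test:
    the X and Y coordinates are re-paired at random many times, the zone
    area is recomputed for each permutation, and the observed Q is
    compared to the permutation null with a one-tailed Z-test.  Includes
    seeded synthetic scatter generators (independent, triangular,
    promotion, humped envelopes) for calibration and power studies, a
    pluggable boundary-line provider hook, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    grDevices,
    graphics,
    jsonlite,
    optparse,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
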