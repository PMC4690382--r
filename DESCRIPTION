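Package: cytomech
Title: Finite-Element Mechanics of the First Embryonic Cell Division
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Incremental finite-element simulation of cytokinesis driven by
    contraction of the equatorial cleavage furrow, with optional mitotic
    spindle extension and vitelline-membrane confinement imposed as sliding
    boundary conditions. Includes structured tetrahedral meshing of
    axisymmetric cell shapes, a linear St. Venant-Kirchhoff elastostatic
    solver with strain-energy accounting, a time-lapse shape-quantification
    pipeline for binary cell masks (furrow and polar axis lengths, cleavage
    window detection, dimensionless elongation curves, vitelline-to-cell
    ratios), stepwise fitting of furrow-width and spindle-length schedules to
    elongation data, population comparison statistics, and a synthetic
    dividing-cell movie generator with exact ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    graphics,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
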