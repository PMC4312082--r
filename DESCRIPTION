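Package: coroshear
Title: Endothelial Shear Stress and Plaque Association in Parametric Coronary Vessels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Links computed endothelial shear stress (ESS) to atherosclerotic
    plaque measures in coronary-artery-like conduits. Generates parametric
    vessel geometries with structured hexahedral O-grid sweep meshes and
    graded near-wall boundary layers, solves steady incompressible laminar
    Newtonian flow with a colocated finite-volume coupled velocity-pressure
    scheme, extracts wall shear stress, stratifies the wall into four
    equal-area ESS quartiles, simulates intravascular-ultrasound pullback
    measurements (intima-media thickness and four-class tissue composition)
    conditioned on the local ESS quartile, and runs the association analysis:
    plaque prevalence tables, chi-square tests, one-way ANOVA with Duncan's
    multiple range test, and cluster-robust logistic marginal models fitted
    by generalized estimating equations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    generics,
    ggplot2,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
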