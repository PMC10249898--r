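Package: eskrig
Title: Geostatistical Mapping and Driver Analysis of Plot-Level Ecosystem Services
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the spatial heterogeneity of plot-level
    ecosystem services from field surveys laid out by grid-random sampling.
    Provides Min-Max normalization and equal-weight composite ecosystem-service
    scores, empirical semivariogram estimation with spherical model fitting and
    nugget-to-sill spatial-dependence classification, ordinary kriging with
    hold-out and leave-one-out cross-validation, Getis-Ord Gi* hot/cold-spot
    detection with distance-band weights, and geographical-detector factor and
    interaction analysis with Jenks natural-breaks discretization. A synthetic
    plot generator simulates lognormal ecosystem-service fields with spherical
    spatial covariance and zonal driver layers with known ground truth, so every
    stage can be validated end-to-end against simulations.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
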