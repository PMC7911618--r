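Package: rangecast
Title: Geodetector-Screened Maximum-Entropy Species Distribution
    Modelling and Range-Change Forecasting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for forecasting the suitable range of a species under
    climate scenarios by combining spatial-stratified-heterogeneity
    variable screening (the geodetector q-statistic with Fisher-Jenks
    natural-breaks stratification and a fishnet response) with a
    presence/background maximum-entropy distribution model (linear,
    quadratic, product, hinge and threshold features under L1
    regularization, clamped projection, cloglog/logistic output).
    Includes ESRI ASCII raster and occurrence-table input/output, ROC/AUC
    and jackknife evaluation, response curves, suitability
    classification, area and range-change summaries, centroid shifts,
    multivariate environmental similarity surfaces (MESS), a synthetic
    virtual-species data generator, and a seeded end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    geosphere,
    ggplot2,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
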