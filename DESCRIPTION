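Package: specfrac
Title: Fractional-Order Derivative Spectroscopy for Canopy Chlorophyll Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for estimating leaf chlorophyll content from
    canopy hyperspectral reflectance. Provides Savitzky-Golay smoothing
    followed by Grunwald-Letnikov fractional-order differentiation (orders
    0-2), empirical vegetation indices, red-edge "trilateral" parameters,
    exhaustive two-band difference-index and soil-adjusted-index correlation
    screening against chlorophyll per unit leaf area and per unit fresh
    weight, and SVM, random-forest and back-propagation neural-network
    regression with repeated-run averaging. Includes a synthetic canopy
    reflectance generator with known latent chlorophyll, water and structure
    parameters so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    e1071,
    nnet,
    randomForest,
    Rcpp,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
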