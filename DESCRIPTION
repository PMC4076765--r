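Package: cpmap
Title: Compliance Potential Mapping of Walking-Based Physical Activity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates joint discrete-continuous models of transport mode
    choice and log-normal trip distance, and multivariate ordered probit
    models of per-mode trip frequency, from household travel-diary data.
    Spatial variation is captured by a quadratic trend surface in home
    coordinates plus distance to the central business district. Fitted
    models are combined by map algebra into rasters of expected total
    daily walking distance, weekly walking minutes, and percent
    compliance with a physical-activity guideline. Includes a synthetic
    travel-survey generator with known ground truth for validating the
    estimators, exact and simulated (GHK) multivariate normal rectangle
    probabilities, and writers for ESRI ASCII grid and CSV raster output.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    MASS,
    nnet,
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    mvtnorm,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
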