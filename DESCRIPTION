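Package: glucopipe
Title: Smartphone Colorimetric Glucose Classification Pipeline
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulation and analysis pipeline for smartphone-based
    colorimetric glucose sensing with an enzymatic (glucose
    oxidase/peroxidase) assay. Generates synthetic well images under a
    Beer-Lambert colour model with configurable lighting, location and
    camera-profile effects; implements the three-stage preprocessing
    chain (grayscale conversion, percentile contrast stretching, bilinear
    resizing); trains and cross-validates a two-block 2-D convolutional
    neural network over 16 concentration classes (50-200 mg/dL); and
    evaluates predictions with confusion-matrix metrics, ISO
    15197-style accuracy bands and range-stratified coefficients of
    determination.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
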