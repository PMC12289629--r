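Package: leafchroma
Title: Leaf Chlorophyll Estimation from RGB Color-Sensor Readings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Computational stack of a handheld colorimetric leaf-chlorophyll
    detector: conversion of raw four-channel (red, green, blue, clear)
    color-sensor intensities into a canonical set of twenty color features
    (clear-normalized RGB indices, HSV, and ten ratio/product indices),
    calibrated five-feature linear models predicting chlorophyll-a,
    chlorophyll-b, and total chlorophyll content (mg/g fresh leaf), the
    multivariate calibration workflow (ordinary least squares and partial
    least squares regression with coefficient-significance screening),
    the spectrophotometric reference assay based on Arnon's equations for
    645/663 nm absorbances of 80% acetone extracts, instrument
    repeatability and stability statistics (coefficient-of-variation
    reports), a synthetic-data generator with planted models for
    end-to-end testing, and a command-line front end emulating the device
    measurement workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    grDevices,
    jsonlite,
    mixOmics,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
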