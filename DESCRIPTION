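Package: cellpopfit
Title: Calibration of Cell Population Growth Models from Time-Series Counts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits canonical cell population dynamics models (exponential,
    logistic, and birth-death-clearance compartment models) to time series
    of live, dead, and total cell counts with replicates. Calibration uses
    Levenberg-Marquardt weighted least squares; fit quality is summarised
    by the weighted sum of squared errors, mean absolute percentage error,
    and reduced chi-squared, with parameter standard errors from the
    scaled covariance of the fit. Competing models are ranked by quality
    of fit. Includes a seeded synthetic high-content-screen generator for
    validating recovery of cytostatic versus cytotoxic drug effects,
    spreadsheet (XLSX/CSV-bundle) input parsing, subsampling utilities for
    sampling-sparsity experiments, and HTML/figure/XML report generation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    grDevices,
    tools,
    minpack.lm,
    deSolve,
    readxl,
    xml2,
    ggplot2,
    withr,
    yaml,
    rlang
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
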