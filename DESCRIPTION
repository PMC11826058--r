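Package: biosensr
Title: Expression-Fraction Characterization of Whole-Cell Biosensors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for characterizing whole-cell biosensors from plate-reader
    time series. Estimates specific growth and reporter production rates by
    forward differences, determines the expression fraction of a heterologous
    reporter by the maximum method (peak fluorescence/OD within an early
    culture window) and by the slope method (linear regression of specific
    production rate on specific growth rate over an automatically selected
    window), and fits Hill dose-response parameters by bounded,
    inverse-variance-weighted nonlinear least squares. A proteome-allocation
    batch-culture simulator generates synthetic microtiter datasets with known
    expression fractions for validating every stage of the analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    minpack.lm,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
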