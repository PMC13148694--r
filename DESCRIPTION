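Package: actimet
Title: Accelerometer Count Calibration to Metabolic Equivalents
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Calibrates wearable accelerometer activity counts against
    indirect-calorimetry energy expenditure. Fits a square-root-scale
    linear model linking epoch counts to metabolic equivalents (METs)
    across device and placement strata, inverts the fitted equations
    into counts/min cut-points for physical-activity intensity bands
    with delta-method confidence intervals, and scores intensity
    classification (confusion matrices, sensitivity, specificity,
    balanced accuracy, one-vs-rest AUC). Includes a synthetic cohort
    simulator (treadmill protocol, device count emulation,
    breath-by-breath oxygen uptake) so the whole pipeline is testable
    without device exports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    MASS,
    lmtest,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    knitr,
    optparse,
    pROC,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
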