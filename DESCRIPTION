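Package: bernroc
Title: Smooth ROC Curve Estimation via Bernstein Polynomials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Nonparametric estimation of receiver operating characteristic
    (ROC) curves by Bernstein polynomial smoothing of the empirical ROC
    curve, with two self-selecting polynomial degrees: one tied to the
    number of unique control marker values (BP) and one tied to the number
    of steps of the empirical ROC curve (BPa).  Also provides the empirical
    ROC estimator, a moment-based binormal baseline, trapezoidal AUC,
    built-in normal and gamma sampling scenarios with exact true ROC curves
    and AUCs, and a Monte Carlo engine that compares curve estimators by
    pointwise mean squared error, relative efficiency, mean integrated
    squared error (MISE) and overall relative efficiency (ORE).  Fitted
    objects support broom-style tidy() and glance() and ggplot2 autoplot();
    a small command line interface drives estimation and simulation runs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
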