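Package: grivus
Title: Dose-Time-Response Surface Modelling and Growth-Rate-Normalised
    Scoring for Live-Cell Imaging Drug Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits a hybrid dose-time-response surface -- a 4-parameter
    logistic dose-response curve whose asymptotes follow logistic growth
    in time -- to cell-count time courses from live-cell imaging drug
    screens. Computes GRIVUS, the growth-rate-inhibition volume under the
    dose-time-response surface, by averaged upper/lower cuboid
    integration of the growth-rate-rescaled surface, normalised by the
    unaffected (no-drug-effect) volume. Supports truncated-window fitting
    and extrapolation of long-term drug response from short time courses,
    quality metrics (MAPE, Pearson and concordance correlation with
    bootstrap confidence intervals), plate-table input/output, a
    command-line interface, and a synthetic plate generator for
    parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
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
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
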