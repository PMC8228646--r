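Package: pneumolag
Title: Distributed Lag Non-Linear Modelling of Climate and Pneumonia
    Admissions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tidyverse-native pipeline for estimating delayed, non-linear
    associations between daily meteorology (mean temperature, relative
    humidity, diurnal temperature range) and low-count hospital admission
    series. Identifies suspected-pneumonia admissions from free-text
    admission reasons, reconstructs missing admission dates, multiply
    imputes missing lengths of stay by predictive mean matching with
    Rubin's-rules pooling, builds natural-cubic-spline crossbases over a
    21-day lag window, fits a zero-inflated negative binomial distributed
    lag non-linear model by maximum likelihood, converts coefficients to
    centered relative-rate surfaces with delta-method intervals, and
    computes backward-perspective attributable fractions with Monte Carlo
    confidence intervals and climate-shift scenarios. A synthetic-data
    module generates meteorology, admission counts and raw records with
    known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    lubridate,
    MASS,
    purrr,
    readr,
    rlang,
    splines,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    glmmTMB,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
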