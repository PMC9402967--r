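Package: aerocast
Title: Hybrid Decomposition-Ensemble Forecasting of Daily Air Pollutant
    Concentrations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@aerocast.dev",
           role = c("aut", "cre"))
Description: Tools for one-step-ahead forecasting of daily concentrations of
    the six routinely monitored air pollutants (PM2.5, PM10, SO2, NO2, CO,
    O3) with a decomposition-ensemble deep-learning pipeline: empirical mode
    decomposition and its noise-assisted variants (EEMD, paired-noise CEEMD,
    adaptive-noise CEEMDAN) split a pollutant series into intrinsic mode
    functions, a small convolutional-recurrent (CNN-LSTM) network forecasts
    each component one day ahead, particle swarm optimization selects the
    shared window length and LSTM cell count, and the component forecasts
    are summed back into a concentration forecast.  Includes a seeded
    synthetic-panel generator with seasonal, trend, autoregressive and
    cross-pollutant structure, forecast evaluation and model-comparison
    reports (RMSE, MAE, two R-squared conventions, percent error
    reductions), and an avoidable-mortality module that converts annual
    mean concentrations, air-quality reference standards and
    exposure-response coefficients into attributable premature deaths with
    confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
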