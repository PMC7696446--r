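Package: cgmforecast
Title: Personalized Short-Horizon Glucose Forecasting from Continuous
    Glucose Monitoring Traces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for building and evaluating personalized short-horizon
    blood-glucose forecasters from continuous glucose monitoring (CGM)
    time series. Includes a synthetic CGM trace simulator (circadian
    baseline, meal excursions, autocorrelated process noise, sensor
    dropout), preprocessing (range filtering, grid regularization,
    reversible scaling), sliding-window sample framing with chronological
    train/test splitting, per-patient recurrent forecasters (simple RNN,
    GRU, LSTM; stacked and bidirectional variants) trained by
    backpropagation through time with RMSprop or Adamax, and clinical
    evaluation via RMSE, MAPE and Clarke error-grid analysis, together
    with experiment runners that compare algorithms, architectures,
    split ratios and training hyper-parameters across a cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    rlang,
    jsonlite,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
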