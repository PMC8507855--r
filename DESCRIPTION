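Package: gapfillr
Title: Long-Interval Gap Filling for Half-Hourly Sensor Temperature Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fills month-scale gaps in half-hourly temperature records using a
    bidirectional LSTM encoder-decoder imputer (BiLSTM-I) anchored on three
    sparse daily manual observations, alongside classical baselines: a
    BRITS-I-style recurrent imputer with temporal decay, and Kalman smoothing
    under basic-structural and ARIMA state-space models. Includes a synthetic
    weather generator (annual and diurnal cycles plus AR(1) weather
    deviations), rolling-window masked training-sample construction,
    manual-to-machine calibration, masked-position accuracy metrics
    (RMSE, MAE, MRE, PCC), and a method-comparison harness.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    withr,
    generics,
    ggplot2,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
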