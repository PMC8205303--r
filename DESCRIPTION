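Package: nsbforecast
Title: Semi-Naive Bayes Forecasting of Dissolved Oxygen Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: One-step-ahead forecasting of dissolved oxygen (and other
    continuous water-quality series) with an enhanced semi-naive Bayes
    classifier over discretized first-order differences. The series is
    differenced, differences are rounded to a fixed sensor resolution and
    treated as categorical symbols, sliding windows over the symbol stream
    provide training samples, rare difference classes are removed with a
    frequency threshold, and an averaged one-dependence (super-parent)
    Bayes model with Laplace smoothing predicts the most probable next
    difference. Includes incremental model updates, JSON model
    persistence, forecast evaluation (MAE, RMSE, MAPE, Willmott's index
    of agreement), the Diebold-Mariano forecast-comparison test, a
    synthetic diurnal sensor-series generator, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
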