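Package: glucobench
Title: Benchmarking Data-Driven Blood Glucose Forecasters on CGM Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable benchmarking pipeline for short-horizon blood glucose
    level forecasting in type 1 diabetes. Simulates cohorts of patient records
    with the structure of continuous glucose monitoring studies (5-minute CGM
    grid, carbohydrate and bolus insulin event logs, an activity channel,
    sensor gaps, train/test split), implements three personalised forecaster
    families (ARIMA/ARIMAX, RBF-kernel support vector regression, and a
    sequence-to-sequence LSTM) in univariate and multivariate modes at 30- and
    60-minute horizons, scores them with regression metrics (RMSE, MAE) and
    clinical metrics (event Matthews correlation, bilinearly interpolated
    surveillance-error score), and compares models with a rank-based
    statistical harness (Friedman omnibus test, Nemenyi post-hoc with Holm
    correction, critical-difference values, exact Wilcoxon signed-rank).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    xml2,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
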