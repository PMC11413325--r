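#' Construct a forecast series
#'
#' Container for model predictions aligned to reference test values at a
#' fixed prediction horizon. All forecasters in the package emit this
#' object on the identical target-time grid for a given patient and
#' horizon, so metric comparisons are paired by construction.
#'
#' @param target_times POSIXct timestamps of the predicted points.
#' @param predicted predictions, mg/dL.
#' @param reference reference values, mg/dL.
#' @param horizon prediction horizon in minutes (30 or 60).
#' @param model model label (`"ctf"`, `"tml"`, `"dnn"`, `"persistence"`).
#' @param input_mode `"univariate"` or `"multivariate"`.
#' @param reference_imputed logical: was the reference value imputed (test
#'   extrapolation fill) rather than observed? Imputed references are
#'   excluded from scoring by default.
#' @return an object of class `forecast_series`.
#' @export
forecast_series <- function(target_times, predicted, reference, horizon,
                            model = "model", input_mode = "univariate",
                            reference_imputed = NULL) {
  n <- length(predicted)
  if (length(reference) != n || length(target_times) != n)
    stopf("predicted, reference and target_times must have equal length")
  structure(
    list(target_times = target_times, predicted = as.numeric(predicted),
         reference = as.numeric(reference),
         reference_imputed = reference_imputed %||% rep(FALSE, n),
         horizon = horizon, model = model, input_mode = input_mode),
    class = "forecast_series")
}

#' @export
print.forecast_series <- function(x, ...) {
  cat(sprintf("<forecast_series> %s/%s, horizon %d min, %d points\n",
              x$model, x$input_mode, x$horizon, length(x$predicted)))
  invisible(x)
}

# scored (reference, predicted) pairs, excluding imputed references by default
scored_pairs <- function(forecast, include_imputed = FALSE) {
  keep <- include_imputed | !forecast$reference_imputed
  if (!any(keep)) stopf("no scored pairs (all references imputed)")
  list(reference = forecast$reference[keep],
       predicted = forecast$predicted[keep])
}

#' Persistence (naive last-value) baseline forecast
#'
#' Predicts the glucose value at `t + horizon` to equal the value observed
#' at `t`. This is the sanity yardstick every trained forecaster should
#' beat at 30 minutes.
#'
#' @param test data frame `time`, `value` (complete, regular glucose test
#'   series); an `imputed` column is propagated to the scoring mask.
#' @param horizon minutes ahead (must be a multiple of the grid spacing).
#' @return a [forecast_series()].
#' @export
persistence_baseline <- function(test, horizon) {
  step <- as.numeric(test$time[2] - test$time[1], units = "mins")
  h <- horizon / step
  if (h != round(h)) stopf("horizon must be a multiple of the grid spacing")
  n <- nrow(test)
  if (n <= h) stopf("test series shorter than the horizon")
  idx <- (h + 1):n
  forecast_series(
    target_times = test$time[idx],
    predicted = test$value[idx - h],
    reference = test$value[idx],
    horizon = horizon, model = "persistence",
    input_mode = "univariate",
    reference_imputed = (test$imputed %||% rep(FALSE, n))[idx])
}
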