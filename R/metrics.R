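#' Root mean square error of a forecast
#'
#' `sqrt(sum((y - yhat)^2) / N)` over scored pairs. Pairs whose reference
#' value was imputed (test-side extrapolation fill) are excluded unless
#' `include_imputed = TRUE`.
#'
#' @param forecast a [forecast_series()].
#' @param include_imputed score imputed reference points too?
#' @return RMSE in mg/dL.
#' @export
rmse <- function(forecast, include_imputed = FALSE) {
  p <- scored_pairs(forecast, include_imputed)
  sqrt(mean((p$reference - p$predicted)^2))
}

#' Mean absolute error of a forecast
#'
#' Mean absolute residual over scored pairs; same scoring mask as [rmse()].
#'
#' @inheritParams rmse
#' @return MAE in mg/dL.
#' @export
mae <- function(forecast, include_imputed = FALSE) {
  p <- scored_pairs(forecast, include_imputed)
  mean(abs(p$reference - p$predicted))
}

#' Classify glucose values into adverse vs normoglycaemic states
#'
#' A value is adverse iff it lies strictly below the hypoglycaemia
#' threshold or strictly above the hyperglycaemia threshold; the boundary
#' values themselves count as normoglycaemic. The defaults, 70 and
#' 180 mg/dL, are the consensus clinical cut-offs.
#'
#' @param value glucose values, mg/dL.
#' @param hypo_threshold,hyper_threshold event thresholds, mg/dL.
#' @return logical vector, `TRUE` for adverse.
#' @export
classify_glycaemic_state <- function(value, hypo_threshold = 70,
                                     hyper_threshold = 180) {
  if (hypo_threshold >= hyper_threshold)
    stopf("hypo_threshold must be below hyper_threshold")
  value < hypo_threshold | value > hyper_threshold
}

#' Matthews correlation coefficient for adverse-event detection
#'
#' Classifies reference and predicted values into adverse vs
#' normoglycaemic states per scored timestamp and computes the binary
#' Matthews correlation `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`,
#' with adverse as the positive class. If any factor of the denominator is
#' zero the coefficient is defined as 0.
#'
#' @inheritParams rmse
#' @param hypo_threshold,hyper_threshold passed to
#'   [classify_glycaemic_state()].
#' @return MCC in \[-1, 1\].
#' @export
mcc_events <- function(forecast, hypo_threshold = 70, hyper_threshold = 180,
                       include_imputed = FALSE) {
  p <- scored_pairs(forecast, include_imputed)
  ref <- classify_glycaemic_state(p$reference, hypo_threshold, hyper_threshold)
  prd <- classify_glycaemic_state(p$predicted, hypo_threshold, hyper_threshold)
  tp <- sum(ref & prd); tn <- sum(!ref & !prd)
  fp <- sum(!ref & prd); fn <- sum(ref & !prd)
  den <- as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (as.numeric(tp) * tn - as.numeric(fp) * fn) / sqrt(den)
}

#' Surveillance-error-grid risk surface
#'
#' Builds the risk lookup used by [seg_risk()]: risk values at every
#' integer (reference, predicted) node on \[0, 600\] x \[0, 600\] mg/dL.
#' The bundled surface is *synthetic*: a clinically shaped analytic
#' surrogate for the published consensus surveillance-error grid, not a
#' digitisation of it. It is zero on the diagonal, non-negative,
#' continuous, unimodal within each reference row with its minimum at the
#' diagonal, on the usual 0-4 risk scale, and penalises the clinically
#' dangerous quadrants more (overprediction during hypoglycaemia,
#' underprediction during hyperglycaemia). Absolute surveillance-error
#' scores therefore emulate, rather than reproduce, scores computed with
#' the published grid.
#'
#' @param type only `"synthetic"` is available.
#' @param validate check the diagonal/positivity/unimodality invariants
#'   after construction.
#' @return an object of class `seg_grid`: list with `risk` (601 x 601
#'   matrix, row = reference, column = predicted, node spacing 1 mg/dL)
#'   and `provenance`.
#' @export
seg_grid <- function(type = "synthetic", validate = TRUE) {
  type <- match.arg(type)
  v <- 0:600
  g <- log((v + 30) / 30)
  dif <- outer(g, g, function(r, p) p - r)       # g(pred) - g(ref) per cell
  over_w <- 1 + 2 / (1 + exp(-(70 - v) / 15))    # overprediction weight by ref
  under_w <- 1 + 2 / (1 + exp(-(v - 180) / 40))  # underprediction weight by ref
  risk <- over_w * pmax(dif, 0) + under_w * pmax(-dif, 0)
  risk <- risk * (4 / max(risk))
  grid <- structure(
    list(risk = risk,
         provenance = "synthetic analytic surrogate surface (glucobench)"),
    class = "seg_grid")
  if (validate) validate_seg_grid(grid)
  grid
}

validate_seg_grid <- function(grid) {
  r <- grid$risk
  if (!is.matrix(r) || nrow(r) != 601 || ncol(r) != 601)
    stopf("malformed SEG grid: expected a 601 x 601 risk matrix")
  if (any(!is.finite(r)) || any(r < 0)) stopf("SEG risk must be finite and >= 0")
  if (any(abs(diag(r)) > 1e-9)) stopf("SEG risk must be zero on the diagonal")
  for (i in seq_len(nrow(r))) {
    row <- r[i, ]
    if (any(diff(row[1:i]) > 1e-9) ||
        (i < length(row) && any(diff(row[i:length(row)]) < -1e-9)))
      stopf("SEG risk row %d is not unimodal with minimum at the diagonal", i)
  }
  invisible(grid)
}

#' Bilinearly interpolated surveillance-error risk
#'
#' Clamps the (reference, predicted) pair to \[0, 600\] mg/dL and
#' interpolates the risk bilinearly among the four surrounding integer
#' grid nodes.
#'
#' @param reference,predicted glucose values, mg/dL (vectorised).
#' @param grid a [seg_grid()].
#' @return risk values.
#' @export
seg_risk <- function(reference, predicted, grid = seg_grid()) {
  if (!inherits(grid, "seg_grid")) stopf("grid must be a seg_grid object")
  r <- pmin(pmax(reference, 0), 600)
  p <- pmin(pmax(predicted, 0), 600)
  r0 <- pmin(floor(r), 599); p0 <- pmin(floor(p), 599)
  fr <- r - r0; fp <- p - p0
  i <- r0 + 1; j <- p0 + 1
  m <- grid$risk
  (1 - fr) * (1 - fp) * m[cbind(i, j)] +
    (1 - fr) * fp * m[cbind(i, j + 1)] +
    fr * (1 - fp) * m[cbind(i + 1, j)] +
    fr * fp * m[cbind(i + 1, j + 1)]
}

#' Mean surveillance-error score of a forecast
#'
#' Average of [seg_risk()] over scored pairs: each patient/model/horizon
#' combination gets one dimensionless risk score.
#'
#' @inheritParams rmse
#' @param grid a [seg_grid()].
#' @return mean risk (>= 0).
#' @export
surveillance_error <- function(forecast, grid = seg_grid(),
                               include_imputed = FALSE) {
  p <- scored_pairs(forecast, include_imputed)
  mean(seg_risk(p$reference, p$predicted, grid))
}

#' Score a forecast with all study metrics
#'
#' One row of the study's metric table: RMSE, MAE, event MCC and
#' surveillance error for a forecast, keyed by patient, model, input mode
#' and horizon.
#'
#' @inheritParams rmse
#' @param patient_id patient label for the row.
#' @param grid a [seg_grid()].
#' @param hypo_threshold,hyper_threshold event thresholds, mg/dL.
#' @return one-row data frame with columns `patient_id`, `model`, `input`,
#'   `horizon`, `rmse`, `mae`, `mcc`, `se`, `n`.
#' @export
score_forecast <- function(forecast, patient_id = "patient",
                           grid = seg_grid(),
                           hypo_threshold = 70, hyper_threshold = 180,
                           include_imputed = FALSE) {
  p <- scored_pairs(forecast, include_imputed)
  data.frame(
    patient_id = patient_id, model = forecast$model,
    input = forecast$input_mode, horizon = forecast$horizon,
    rmse = rmse(forecast, include_imputed),
    mae = mae(forecast, include_imputed),
    mcc = mcc_events(forecast, hypo_threshold, hyper_threshold,
                     include_imputed),
    se = surveillance_error(forecast, grid, include_imputed),
    n = length(p$reference))
}

#' Colour-coded surveillance-error-grid plot
#'
#' Scatter of (reference, predicted) pairs over the colour-coded risk
#' surface, axes 0-600 mg/dL.
#'
#' @param forecast a [forecast_series()].
#' @param grid a [seg_grid()].
#' @param file optional path; when given the plot is also written there
#'   (format from the extension, e.g. `.png` or `.svg`).
#' @return the ggplot object, invisibly.
#' @export
plot_seg <- function(forecast, grid = seg_grid(), file = NULL) {
  p <- scored_pairs(forecast, include_imputed = TRUE)
  sub <- seq(1, 601, by = 4)                   # thin the raster for drawing
  surf <- expand.grid(reference = sub - 1, predicted = sub - 1)
  surf$risk <- as.numeric(grid$risk[sub, sub])
  pts <- data.frame(reference = p$reference, predicted = p$predicted)
  gg <- ggplot2::ggplot(surf,
                        ggplot2::aes(x = reference, y = predicted)) +
    ggplot2::geom_raster(ggplot2::aes(fill = risk)) +
    ggplot2::scale_fill_gradientn(
      colours = c("#2e7d32", "#fdd835", "#fb8c00", "#c62828"),
      limits = c(0, 4), name = "risk") +
    ggplot2::geom_point(data = pts, size = 0.4, alpha = 0.6) +
    ggplot2::coord_fixed(xlim = c(0, 600), ylim = c(0, 600), expand = FALSE) +
    ggplot2::labs(x = "reference glucose (mg/dL)",
                  y = "predicted glucose (mg/dL)",
                  title = sprintf("%s / %s, %d-min horizon",
                                  forecast$model, forecast$input_mode,
                                  forecast$horizon)) +
    ggplot2::theme_minimal()
  if (!is.null(file)) ggplot2::ggsave(file, gg, width = 6, height = 5, dpi = 150)
  invisible(gg)
}
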