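#' Impute missing values in a regular series
#'
#' Fills gaps in a regularly sampled series. In `"train"` mode each gap is
#' linearly interpolated between its nearest observed neighbours (gaps at the
#' boundary fall back to the nearest observed value, or to causal
#' extrapolation at the end). In `"test"` mode fills are strictly causal:
#' each gap is linearly extrapolated forward from the last two observed
#' points before it, so no future value can leak into a test-set fill.
#' Observed points are never altered and every point carries an `imputed`
#' flag.
#'
#' @param series data frame with columns `time`, `value` (`NA` where
#'   missing) and optionally `missing`.
#' @param mode `"train"` (interpolate) or `"test"` (extrapolate).
#' @return the series with `value` complete and an `imputed` logical column.
#' @export
impute_series <- function(series, mode = c("train", "test")) {
  mode <- match.arg(mode)
  v <- series$value
  miss <- if ("missing" %in% names(series)) series$missing | is.na(v) else is.na(v)
  obs <- which(!miss)
  if (length(obs) < 2) stopf("need at least 2 observed points to impute")
  out <- v
  if (any(miss)) {
    x <- as.numeric(series$time)
    if (mode == "train") {
      out[miss] <- approx(x[obs], v[obs], xout = x[miss], rule = 2)$y
    } else {
      for (i in which(miss)) {
        prev <- obs[obs < i]
        if (length(prev) >= 2) {
          i1 <- prev[length(prev) - 1]; i2 <- prev[length(prev)]
          slope <- (v[i2] - v[i1]) / (x[i2] - x[i1])
          out[i] <- v[i2] + slope * (x[i] - x[i2])
        } else if (length(prev) == 1) {
          out[i] <- v[prev]
        } else {
          # gap before any observation: backfill from first observed value
          out[i] <- v[obs[1]]
        }
      }
    }
  }
  series$value <- out
  series$missing <- miss
  series$imputed <- miss
  series
}

#' Zero-fill an event log onto a regular grid
#'
#' Converts a timestamped event series (meal carbohydrates, bolus doses)
#' into a regular series that is zero except at grid points carrying an
#' event. Events are binned to the nearest grid point; simultaneous events
#' in one bin are summed, conserving total grams/units.
#'
#' @param events data frame with columns `time`, `value`; may be empty.
#' @param grid POSIXct vector of regular grid timestamps.
#' @return data frame `time`, `value` on the grid.
#' @export
zero_fill_events <- function(events, grid) {
  if (!is_regular_grid(grid)) stopf("grid must be regular")
  out <- numeric(length(grid))
  if (nrow(events)) {
    gx <- as.numeric(grid)
    step <- gx[2] - gx[1]
    idx <- round((as.numeric(events$time) - gx[1]) / step) + 1
    keep <- idx >= 1 & idx <= length(grid)
    for (j in which(keep)) out[idx[j]] <- out[idx[j]] + events$value[j]
  }
  data.frame(time = grid, value = out)
}

#' Align an activity channel to the glucose grid
#'
#' Downsamples a 1-minute activity series to the 5-minute glucose grid by
#' keeping, for each glucose timestamp, the temporally nearest activity
#' sample and discarding the remainder; ties go to the earlier sample. An
#' already 5-minute series is matched to the grid unchanged.
#'
#' @param activity data frame `time`, `value`.
#' @param glucose_grid POSIXct grid to align to.
#' @return data frame `time` (the glucose grid), `value`.
#' @export
align_activity <- function(activity, glucose_grid) {
  if (!nrow(activity)) stopf("activity series is empty")
  at <- as.numeric(activity$time); gt <- as.numeric(glucose_grid)
  if (max(at) < min(gt) || min(at) > max(gt))
    stopf("activity and glucose grids do not overlap")
  idx <- vapply(gt, function(g) {
    d <- abs(at - g)
    which(d == min(d))[1]              # earlier sample wins ties
  }, integer(1))
  data.frame(time = glucose_grid, value = activity$value[idx])
}

#' Trim channels to their common time span
#'
#' Restricts every channel to the intersection of all channels' spans,
#' discarding timestamps at the beginning/end that are unavailable in some
#' channel (e.g. because sensors were put on at different times).
#'
#' @param channels named list of data frames with a `time` column.
#' @return the list with each element restricted to the common span.
#' @export
trim_boundaries <- function(channels) {
  if (!length(channels)) stopf("need at least one channel")
  lo <- max(vapply(channels, function(ch) min(as.numeric(ch$time)), 0))
  hi <- min(vapply(channels, function(ch) max(as.numeric(ch$time)), 0))
  if (lo > hi) stopf("channels have empty common span")
  lapply(channels, function(ch) {
    x <- as.numeric(ch$time)
    out <- ch[x >= lo & x <= hi, , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Reframe series as a supervised sliding-window task
#'
#' Turns complete, aligned 5-minute channels into history/target pairs for
#' supervised multi-step forecasting: each input is the last `history_length`
#' steps of the selected channels (glucose only in univariate mode; glucose,
#' carb, bolus, activity stacked in that fixed order in multivariate mode)
#' and each target is the next `horizon` glucose values. Windows slide one
#' step at a time, giving `N - L - H + 1` pairs for a series of length `N`.
#'
#' @param channels named list of equal-length aligned series (data frames
#'   `time`, `value`); must contain `glucose`, and `carb`, `bolus`,
#'   `activity` for multivariate mode. A `reference_imputed` logical vector
#'   attribute per glucose point is taken from a `glucose$imputed` column
#'   when present.
#' @param history_length window length L in steps.
#' @param horizon forecast horizon H in steps.
#' @param mode `"univariate"` or `"multivariate"`.
#' @return an object of class `supervised_frame`: list with `inputs`
#'   (list of L x C matrices), `targets` (list of H vectors), `target_times`
#'   (time of each final-step target), `target_imputed`, `channels`,
#'   `history_length`, `horizon`.
#' @export
reframe <- function(channels, history_length, horizon,
                    mode = c("univariate", "multivariate")) {
  mode <- match.arg(mode)
  chan_names <- if (mode == "univariate") "glucose" else
    c("glucose", "carb", "bolus", "activity")
  missing_ch <- setdiff(chan_names, names(channels))
  if (length(missing_ch)) stopf("missing channels: %s",
                                paste(missing_ch, collapse = ", "))
  n <- nrow(channels$glucose)
  lens <- vapply(channels[chan_names], nrow, 0L)
  if (!all(lens == n)) stopf("channels must have equal length")
  L <- history_length; H <- horizon
  if (n <= L + H - 1) stopf("series too short for L=%d, H=%d", L, H)
  mat <- vapply(chan_names, function(ch) channels[[ch]]$value, numeric(n))
  y <- channels$glucose$value
  imput <- channels$glucose$imputed %||% rep(FALSE, n)
  n_pairs <- n - L - H + 1
  inputs <- vector("list", n_pairs); targets <- vector("list", n_pairs)
  for (i in seq_len(n_pairs)) {
    inputs[[i]] <- mat[i:(i + L - 1), , drop = FALSE]
    targets[[i]] <- y[(i + L):(i + L + H - 1)]
  }
  final_idx <- (L + H):n
  structure(
    list(inputs = inputs, targets = targets,
         target_times = channels$glucose$time[final_idx],
         target_imputed = imput[final_idx],
         channels = chan_names, history_length = L, horizon = H, mode = mode),
    class = "supervised_frame")
}

#' @export
print.supervised_frame <- function(x, ...) {
  cat(sprintf("<supervised_frame> %d pairs, L=%d steps x %d channels -> H=%d steps (%s)\n",
              length(x$inputs), x$history_length, length(x$channels),
              x$horizon, x$mode))
  invisible(x)
}

# flatten a supervised frame into an (n x L*C) design matrix and final-step target
frame_design <- function(frame) {
  X <- t(vapply(frame$inputs, as.numeric,
                numeric(frame$history_length * length(frame$channels))))
  y <- vapply(frame$targets, function(t) t[frame$horizon], 0)
  list(X = X, y = y)
}

#' Preprocess a patient record into aligned model-ready channels
#'
#' Applies the full chain: impute glucose (interpolation on the training
#' side, causal extrapolation on the test side), zero-fill carb and bolus
#' events onto the glucose grid, align the activity channel (downsampling
#' 1-minute activity to the nearest glucose timestamp), and trim all
#' channels to their common span.
#'
#' @param record a [patient_record()].
#' @param mode `"train"` or `"test"` (controls the imputation rule).
#' @return named list of aligned series `glucose`, `carb`, `bolus`,
#'   `activity`, each a data frame on the common 5-min grid; glucose carries
#'   an `imputed` column.
#' @export
preprocess_record <- function(record, mode = c("train", "test")) {
  mode <- match.arg(mode)
  glucose <- impute_series(record$glucose, mode)
  grid <- glucose$time
  channels <- list(
    glucose = glucose,
    carb = zero_fill_events(record$carb, grid),
    bolus = zero_fill_events(record$bolus, grid),
    activity = align_activity(record$activity, grid))
  trim_boundaries(channels)
}
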