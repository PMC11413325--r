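#' Simulation configuration for a synthetic CGM cohort
#'
#' Bundles and validates every knob of the synthetic patient-record
#' generator. Defaults mirror the structure of the CGM field studies the
#' package emulates: roughly eight weeks of 5-minute glucose readings per
#' patient with the final ten days held out for testing, six patients per
#' cohort, self-reported carbohydrate and bolus events, and one activity
#' channel (heart rate every 5 min, or acceleration magnitude every minute).
#'
#' @param n_patients patients in the cohort.
#' @param duration_days total record length in days.
#' @param test_days final days held out for testing (half-open split: the
#'   boundary timestamp belongs to the test side).
#' @param sample_interval glucose sampling interval in minutes; must divide 60.
#' @param basal_glucose fasting set point in mg/dL that the simulated glucose
#'   reverts to between meals.
#' @param meal_rate expected meals per day (daily Poisson count, times drawn
#'   in waking hours).
#' @param carb_mean,carb_sd meal carbohydrate size distribution in grams
#'   (Gaussian, truncated below at 10 g).
#' @param carb_to_bolus_ratio grams of carbohydrate covered by one unit of
#'   bolus insulin; each meal triggers a bolus of `carb / ratio` units with
#'   small timing jitter.
#' @param bolus_error_sd relative standard deviation of the patient's carb
#'   estimate when dosing: boluses cover `carb * N(1, sd) / ratio` units,
#'   so dosing errors create realistic hypo- and hyperglycaemic
#'   excursions.
#' @param meal_absorption_peak minutes from meal to peak glucose appearance.
#' @param insulin_action_peak minutes from bolus to peak glucose-lowering
#'   action.
#' @param carb_effect total glucose rise per gram of carbohydrate before
#'   mean reversion, mg/dL per g (spread over the absorption kernel).
#' @param activity_mode `"heart_rate_5min"` or `"accel_magnitude_1min"`.
#' @param activity_effect glucose-lowering coefficient per standardised unit
#'   of above-baseline activity, mg/dL per 5-min step.
#' @param gap_rate expected sensor gaps per day (see [inject_gaps()]).
#' @param gap_mean,gap_sd gap length distribution in minutes.
#' @param noise_sd stationary standard deviation of the per-step noise
#'   drift, mg/dL.
#' @param noise_rho lag-1 autocorrelation of the noise drift. CGM traces
#'   are smooth: sensor filtering and physiological inertia make the rate
#'   of change persistent, so the disturbance entering each step is an
#'   AR(1) process rather than white noise; 0 recovers i.i.d. increments.
#' @param mean_reversion_rate fraction of the distance to `basal_glucose`
#'   recovered per 5-min step.
#' @param seed master seed; patient `i` uses substream `seed + i`.
#'
#' @return an object of class `simulation_config` (a validated list).
#' @seealso [simulate_patient()], [simulate_cohort()], [inject_gaps()]
#' @export
simulation_config <- function(n_patients = 6,
                              duration_days = 56,
                              test_days = 10,
                              sample_interval = 5,
                              basal_glucose = 130,
                              meal_rate = 4,
                              carb_mean = 45,
                              carb_sd = 20,
                              carb_to_bolus_ratio = 10,
                              bolus_error_sd = 0.2,
                              meal_absorption_peak = 60,
                              insulin_action_peak = 75,
                              carb_effect = 5,
                              activity_mode = c("heart_rate_5min",
                                                "accel_magnitude_1min"),
                              activity_effect = 0.6,
                              gap_rate = 1,
                              gap_mean = 30,
                              gap_sd = 20,
                              noise_sd = 2.5,
                              noise_rho = 0.8,
                              mean_reversion_rate = 0.05,
                              seed = 1L) {
  activity_mode <- match.arg(activity_mode)
  cfg <- list(
    n_patients = as.integer(n_patients), duration_days = duration_days,
    test_days = test_days, sample_interval = sample_interval,
    basal_glucose = basal_glucose, meal_rate = meal_rate,
    carb_mean = carb_mean, carb_sd = carb_sd,
    carb_to_bolus_ratio = carb_to_bolus_ratio,
    bolus_error_sd = bolus_error_sd,
    meal_absorption_peak = meal_absorption_peak,
    insulin_action_peak = insulin_action_peak, carb_effect = carb_effect,
    activity_mode = activity_mode, activity_effect = activity_effect,
    gap_rate = gap_rate, gap_mean = gap_mean, gap_sd = gap_sd,
    noise_sd = noise_sd, noise_rho = noise_rho,
    mean_reversion_rate = mean_reversion_rate,
    seed = as.integer(seed))
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_simulation_config <- function(cfg) {
  if (cfg$duration_days <= cfg$test_days || cfg$test_days < 0)
    stopf("need duration_days > test_days >= 0 (got %s, %s)",
          cfg$duration_days, cfg$test_days)
  if (cfg$duration_days <= 0) stopf("duration_days must be positive")
  if (60 %% cfg$sample_interval != 0)
    stopf("sample_interval must divide 60 (got %s)", cfg$sample_interval)
  for (nm in c("meal_rate", "carb_mean", "carb_sd", "gap_rate", "gap_mean",
               "gap_sd", "noise_sd", "carb_effect", "activity_effect",
               "bolus_error_sd"))
    if (cfg[[nm]] < 0) stopf("%s must be non-negative", nm)
  if (cfg$carb_to_bolus_ratio <= 0) stopf("carb_to_bolus_ratio must be positive")
  if (cfg$mean_reversion_rate < 0 || cfg$mean_reversion_rate > 1)
    stopf("mean_reversion_rate must be in [0, 1]")
  if (abs(cfg$noise_rho %||% 0) >= 1) stopf("noise_rho must lie in (-1, 1)")
  if (cfg$n_patients < 1) stopf("n_patients must be at least 1")
  invisible(cfg)
}

#' Construct a patient record
#'
#' Low-level constructor for the container holding one patient's aligned
#' multichannel series: a glucose series on a regular grid with a per-point
#' missingness flag, carbohydrate and bolus event logs, one activity channel,
#' and the timestamp separating training from testing (half-open: the split
#' timestamp itself belongs to the test side).
#'
#' @param patient_id identifier string.
#' @param cohort cohort label.
#' @param glucose data frame with columns `time` (POSIXct, strictly
#'   increasing regular grid), `value` (mg/dL, `NA` where missing) and
#'   `missing` (logical).
#' @param carb,bolus event data frames with columns `time`, `value`
#'   (grams / units, non-negative); may have zero rows.
#' @param activity data frame with columns `time`, `value`.
#' @param activity_mode resolution/meaning of the activity channel.
#' @param sample_interval glucose grid spacing, minutes.
#' @param split_time POSIXct train/test boundary.
#' @return an object of class `patient_record`.
#' @export
patient_record <- function(patient_id, cohort, glucose, carb, bolus, activity,
                           activity_mode, sample_interval, split_time) {
  rec <- structure(
    list(patient_id = as.character(patient_id), cohort = as.character(cohort),
         glucose = glucose, carb = carb, bolus = bolus, activity = activity,
         activity_mode = activity_mode, sample_interval = sample_interval,
         split_time = split_time),
    class = "patient_record")
  validate_patient_record(rec)
  rec
}

validate_patient_record <- function(rec) {
  g <- rec$glucose
  if (!all(c("time", "value", "missing") %in% names(g)))
    stopf("glucose needs columns time, value, missing")
  if (!is_regular_grid(g$time, rec$sample_interval))
    stopf("glucose timestamps must be a strictly increasing regular %s-min grid",
          rec$sample_interval)
  obs <- g$value[!g$missing]
  if (any(obs < 40 - 1e-9 | obs > 400 + 1e-9, na.rm = TRUE))
    stopf("glucose values must lie in [40, 400] mg/dL")
  for (ch in c("carb", "bolus"))
    if (nrow(rec[[ch]]) && any(rec[[ch]]$value < 0))
      stopf("%s amounts must be non-negative", ch)
  invisible(rec)
}

#' @export
print.patient_record <- function(x, ...) {
  span <- range(x$glucose$time)
  cat(sprintf("<patient_record> %s (cohort %s)\n", x$patient_id, x$cohort))
  cat(sprintf("  glucose : %d points on a %d-min grid, %.1f%% missing\n",
              nrow(x$glucose), x$sample_interval,
              100 * mean(x$glucose$missing)))
  cat(sprintf("  carb    : %d events | bolus: %d events | activity (%s): %d points\n",
              nrow(x$carb), nrow(x$bolus), x$activity_mode, nrow(x$activity)))
  cat(sprintf("  span    : %s .. %s | split at %s\n",
              format(span[1]), format(span[2]), format(x$split_time)))
  invisible(x)
}

# non-negative unimodal impulse-response kernel on the 5-min grid,
# peaking at `peak` minutes, normalised to unit sum (gamma-like shape)
impulse_kernel <- function(peak_minutes, step_minutes, horizon_minutes = NULL) {
  horizon_minutes <- horizon_minutes %||% (6 * peak_minutes)
  tau <- seq(step_minutes, horizon_minutes, by = step_minutes)
  k <- (tau / peak_minutes) * exp(1 - tau / peak_minutes)
  k / sum(k)
}

#' Simulate one patient record
#'
#' Discrete-time generative model on the glucose grid:
#' `G[t+1] = G[t] + k_rev (G_basal - G[t]) + meal inputs - insulin inputs -
#' activity effect + noise`, where meal and insulin inputs are the convolution
#' of the event logs with non-negative unimodal impulse-response kernels
#' peaking at the configured lags, and the result is clamped to
#' \[40, 400\] mg/dL. Meals arrive as a daily Poisson process in waking hours;
#' each meal triggers a bolus of `carb / carb_to_bolus_ratio` units with a
#' few minutes of timing jitter. The activity channel subtracts a small
#' amount of glucose when above its baseline, so multivariate forecasters
#' have genuine exogenous signal. Deterministic given `(seed, patient_index)`.
#'
#' @param config a [simulation_config()].
#' @param patient_index zero-based index of the patient inside the cohort;
#'   selects the RNG substream `seed + patient_index`.
#' @return a [patient_record()] with no missing points (see [inject_gaps()]).
#' @export
simulate_patient <- function(config, patient_index = 0L) {
  validate_simulation_config(config)
  if (patient_index < 0 || patient_index >= config$n_patients)
    stopf("patient_index must be in [0, n_patients)")
  with_seed(config$seed + patient_index, {
    step <- config$sample_interval
    n <- config$duration_days * 24 * 60 / step
    t0 <- .gb_origin()
    times <- t0 + seq(0, by = step * 60, length.out = n)

    # meal + bolus event logs
    meal_t <- numeric(0); meal_g <- numeric(0)
    for (day in seq_len(config$duration_days) - 1) {
      m <- rpois(1, config$meal_rate)
      if (m > 0) {
        tt <- sort(runif(m, 6 * 60, 22 * 60)) + day * 24 * 60
        gg <- pmax(10, rnorm(m, config$carb_mean, config$carb_sd))
        meal_t <- c(meal_t, tt); meal_g <- c(meal_g, gg)
      }
    }
    bolus_t <- meal_t + rnorm(length(meal_t), 0, 5)
    carb_estimate <- meal_g * pmax(0.3, rnorm(length(meal_t), 1,
                                              config$bolus_error_sd))
    bolus_u <- round(carb_estimate / config$carb_to_bolus_ratio, 1)

    # activity channel
    if (config$activity_mode == "heart_rate_5min") {
      at <- times
      tod <- (as.numeric(at - t0) / 3600) %% 24
      av <- 70 + 8 * sin(2 * pi * (tod - 14) / 24) + rnorm(n, 0, 4) +
        40 * (runif(n) < 0.01)            # occasional exercise spikes
      av <- pmax(45, av)
    } else {
      n1 <- config$duration_days * 24 * 60
      at <- t0 + seq(0, by = 60, length.out = n1)
      av <- abs(rnorm(n1, 0.05, 0.05)) + 1.5 * (runif(n1) < 0.005)
    }

    # standardised above-baseline activity on the glucose grid
    if (config$activity_mode == "heart_rate_5min") {
      act5 <- av
    } else {
      act5 <- av[seq(1, length(av), by = step)]
    }
    az <- pmax(0, (act5 - median(act5)) / max(sd(act5), 1e-9))

    # event inputs convolved with the impulse kernels (per-step increments)
    meal_in <- numeric(n); ins_in <- numeric(n)
    km <- impulse_kernel(config$meal_absorption_peak, step)
    ki <- impulse_kernel(config$insulin_action_peak, step)
    bin <- function(tmin) pmin(pmax(round(tmin / step) + 1, 1), n)
    ins_gain <- config$carb_effect * config$carb_to_bolus_ratio
    for (j in seq_along(meal_t)) {
      i0 <- bin(meal_t[j]); idx <- i0 + seq_along(km) - 1; keep <- idx <= n
      meal_in[idx[keep]] <- meal_in[idx[keep]] +
        meal_g[j] * config$carb_effect * km[keep]
    }
    for (j in seq_along(bolus_t)) {
      i0 <- bin(bolus_t[j]); idx <- i0 + seq_along(ki) - 1; keep <- idx <= n
      ins_in[idx[keep]] <- ins_in[idx[keep]] + bolus_u[j] * ins_gain * ki[keep]
    }

    # smooth disturbance: AR(1) drift with stationary sd = noise_sd
    eps <- numeric(n)
    if (config$noise_sd > 0) {
      rho <- config$noise_rho %||% 0
      innov <- rnorm(n, 0, config$noise_sd * sqrt(1 - rho^2))
      eps[1] <- rnorm(1, 0, config$noise_sd)
      for (t in 2:n) eps[t] <- rho * eps[t - 1] + innov[t]
    }
    g <- numeric(n)
    g[1] <- config$basal_glucose
    k <- config$mean_reversion_rate
    for (t in seq_len(n - 1)) {
      g[t + 1] <- g[t] + k * (config$basal_glucose - g[t]) +
        meal_in[t] - ins_in[t] - config$activity_effect * az[t] + eps[t]
      g[t + 1] <- min(400, max(40, g[t + 1]))
    }

    split_time <- t0 + (config$duration_days - config$test_days) * 86400
    patient_record(
      patient_id = sprintf("sim%03d", patient_index + 1),
      cohort = "synthetic",
      glucose = data.frame(time = times, value = g,
                           missing = FALSE, imputed = FALSE),
      carb = data.frame(time = t0 + round(meal_t * 60), value = meal_g),
      bolus = data.frame(time = t0 + round(bolus_t * 60), value = bolus_u),
      activity = data.frame(time = at, value = av),
      activity_mode = config$activity_mode,
      sample_interval = step,
      split_time = split_time)
  })
}

#' Mark sensor gaps in a record
#'
#' Randomly places missing intervals in the glucose channel according to
#' `gap_rate` gaps/day with Gaussian lengths, emulating CGM sensor dropouts.
#' Timestamps are never removed: values inside a gap are set to `NA` and
#' flagged `missing`. Deterministic given the config seed and the patient id.
#'
#' @param record a [patient_record()] on a regular grid.
#' @param config a [simulation_config()]; uses `gap_rate`, `gap_mean`,
#'   `gap_sd` and `seed`.
#' @return the record with gaps flagged.
#' @export
inject_gaps <- function(record, config) {
  if (config$gap_rate == 0) return(record)
  expected_missing <- config$gap_rate * config$gap_mean / (24 * 60)
  if (expected_missing > 0.5)
    stopf("gap configuration implies >50%% expected missingness")
  days <- as.numeric(diff(range(record$glucose$time)), units = "days")
  with_seed(config$seed + 10000L + sum(utf8ToInt(record$patient_id)), {
    n_gaps <- rpois(1, config$gap_rate * days)
    g <- record$glucose
    if (n_gaps > 0) {
      span_secs <- as.numeric(max(g$time) - min(g$time), units = "secs")
      starts <- sort(runif(n_gaps, 0, span_secs))
      lens <- pmax(config$sample_interval %||% record$sample_interval,
                   rnorm(n_gaps, config$gap_mean, config$gap_sd)) * 60
      t0 <- as.numeric(g$time[1])
      for (j in seq_len(n_gaps)) {
        sel <- as.numeric(g$time) >= t0 + starts[j] &
               as.numeric(g$time) <  t0 + starts[j] + lens[j]
        g$missing[sel] <- TRUE
      }
      g$value[g$missing] <- NA_real_
      record$glucose <- g
    }
    record
  })
}

#' Fraction of missing glucose points
#' @param record a [patient_record()].
#' @return missing points divided by total points.
#' @export
missing_fraction <- function(record) mean(record$glucose$missing)

#' Count contiguous missing runs in the glucose channel
#' @param record a [patient_record()].
#' @return number of maximal missing intervals.
#' @export
gap_count <- function(record) {
  m <- record$glucose$missing
  sum(diff(c(FALSE, m)) == 1)
}

#' Split a record into train and test views
#'
#' The test view contains exactly the final `test_days` of every channel,
#' the train view the remainder; the boundary timestamp belongs to the test
#' side (half-open convention).
#'
#' @param record a [patient_record()].
#' @param test_days days held out at the end; defaults to the split already
#'   stored in the record.
#' @return `list(train = , test = )` of patient records.
#' @export
split_train_test <- function(record, test_days = NULL) {
  span <- range(record$glucose$time)
  if (is.null(test_days)) {
    split_time <- record$split_time
  } else {
    total_days <- as.numeric(span[2] - span[1], units = "days")
    if (test_days > total_days) stopf("record shorter than test_days")
    split_time <- span[2] + record$sample_interval * 60 - test_days * 86400
  }
  cut_rec <- function(rec, keep_fun) {
    rec$glucose <- rec$glucose[keep_fun(rec$glucose$time), , drop = FALSE]
    rec$carb <- rec$carb[keep_fun(rec$carb$time), , drop = FALSE]
    rec$bolus <- rec$bolus[keep_fun(rec$bolus$time), , drop = FALSE]
    rec$activity <- rec$activity[keep_fun(rec$activity$time), , drop = FALSE]
    rownames(rec$glucose) <- NULL
    rec
  }
  train <- cut_rec(record, function(t) t < split_time)
  test <- cut_rec(record, function(t) t >= split_time)
  train$split_time <- test$split_time <- split_time
  list(train = train, test = test)
}

#' Simulate a cohort of patient records
#'
#' Runs [simulate_patient()] for each patient index and applies
#' [inject_gaps()] to each record.
#'
#' @param config a [simulation_config()].
#' @return list of [patient_record()] objects.
#' @export
simulate_cohort <- function(config) {
  lapply(seq_len(config$n_patients) - 1L, function(i)
    inject_gaps(simulate_patient(config, i), config))
}
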