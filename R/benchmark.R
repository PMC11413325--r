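# End-to-end orchestration: configuration, the per-patient
# preprocess -> fit -> forecast -> score loop, the statistical layer on the
# resulting metric tables, and the replay path that recomputes the
# statistical layer directly from published per-patient metric values.

#' Benchmark configuration
#'
#' @param cohort a [simulation_config()] for a synthetic cohort, or a
#'   character vector of Ohio-style XML file paths.
#' @param models subset of `c("ctf", "tml", "dnn")`.
#' @param input_modes subset of `c("univariate", "multivariate")`.
#' @param horizons subset of `c(30, 60)` minutes.
#' @param history_length supervised window length L in steps.
#' @param arima_search_max AR/MA order search cap for the CTF model.
#' @param svr_spaces list with `gamma`, `C`, `epsilon` search spaces.
#' @param lstm LSTM settings: list with `hidden_units`, `dense_units`,
#'   `epochs`, `runs`; horizon and history come from the benchmark.
#' @param hypo_threshold,hyper_threshold adverse-event thresholds, mg/dL.
#' @param include_imputed score imputed reference points too?
#' @param alpha significance level of the statistical layer.
#' @param seed master seed for every random stage.
#' @return an object of class `benchmark_config`.
#' @export
benchmark_config <- function(cohort = simulation_config(),
                             models = c("ctf", "tml"),
                             input_modes = c("univariate", "multivariate"),
                             horizons = c(30),
                             history_length = 12,
                             arima_search_max = 2,
                             svr_spaces = list(gamma = c(0.1, 1, 10, 100),
                                               C = c(0.001, 0.01, 0.1, 1),
                                               epsilon = c(0.01, 0.1, 1, 10)),
                             lstm = list(hidden_units = 32, dense_units = 32,
                                         epochs = 30, runs = 3),
                             hypo_threshold = 70, hyper_threshold = 180,
                             include_imputed = FALSE,
                             alpha = 0.05,
                             seed = 1L) {
  models <- match.arg(models, c("ctf", "tml", "dnn"), several.ok = TRUE)
  input_modes <- match.arg(input_modes, c("univariate", "multivariate"),
                           several.ok = TRUE)
  if (!length(horizons) || !all(horizons %% 5 == 0))
    stopf("horizons must be non-empty multiples of 5 minutes")
  if (alpha <= 0 || alpha >= 1) stopf("alpha must be in (0, 1)")
  structure(list(cohort = cohort, models = models, input_modes = input_modes,
                 horizons = horizons, history_length = history_length,
                 arima_search_max = arima_search_max, svr_spaces = svr_spaces,
                 lstm = lstm, hypo_threshold = hypo_threshold,
                 hyper_threshold = hyper_threshold,
                 include_imputed = include_imputed, alpha = alpha,
                 seed = as.integer(seed)),
            class = "benchmark_config")
}

# subset a supervised frame by pair index
frame_subset <- function(frame, idx) {
  frame$inputs <- frame$inputs[idx]
  frame$targets <- frame$targets[idx]
  frame$target_times <- frame$target_times[idx]
  frame$target_imputed <- frame$target_imputed[idx]
  frame
}

# build matching train/test frames over the concatenated channels so that
# test windows may reach back into the training span; test targets land on
# exactly the persistence-baseline grid (origins inside the test span)
build_frames <- function(channels_train, channels_test, history_length,
                         horizon_steps, mode) {
  full <- lapply(names(channels_train), function(ch)
    rbind(channels_train[[ch]], channels_test[[ch]]))
  names(full) <- names(channels_train)
  n_tr <- nrow(channels_train$glucose)
  frame <- reframe(full, history_length, horizon_steps, mode)
  L <- history_length; H <- horizon_steps
  final_idx <- (L + H):nrow(full$glucose)     # final target index per pair
  train_idx <- which(final_idx <= n_tr)
  test_idx <- which(final_idx >= n_tr + H + 1)
  list(train = frame_subset(frame, train_idx),
       test = frame_subset(frame, test_idx))
}

# run every configured forecaster for one patient, one horizon
forecast_patient <- function(record, config, horizon) {
  parts <- split_train_test(record)
  ch_tr <- preprocess_record(parts$train, "train")
  ch_te <- preprocess_record(parts$test, "test")
  step <- record$sample_interval
  h <- horizon / step
  L <- config$history_length
  manifest <- list()
  out <- list()

  for (mode in config$input_modes) {
    if ("ctf" %in% config$models) {
      d <- determine_d(ch_tr$glucose$value, alpha = config$alpha)$d
      ord <- select_arima_order(ch_tr$glucose$value, d,
                                search_max = config$arima_search_max)
      fc <- fit_predict_ctf(ch_tr, ch_te, ord, horizon, mode)
      out[[paste("ctf", mode, sep = ".")]] <- list(fc)
      manifest[[paste("ctf", mode, sep = ".")]] <-
        list(order = ord[c("p", "d", "q")])
    }
    frames <- build_frames(ch_tr, ch_te, L, h, mode)
    if ("tml" %in% config$models) {
      params <- grid_search_svr(frames$train,
                                gamma_space = config$svr_spaces$gamma,
                                C_space = config$svr_spaces$C,
                                epsilon_space = config$svr_spaces$epsilon)
      out[[paste("tml", mode, sep = ".")]] <-
        list(fit_predict_tml(frames$train, frames$test, params))
      manifest[[paste("tml", mode, sep = ".")]] <-
        params[c("gamma", "C", "epsilon")]
    }
    if ("dnn" %in% config$models) {
      spec <- lstm_spec(history_length = L, horizon_steps = h,
                        hidden_units = config$lstm$hidden_units %||% 32,
                        dense_units = config$lstm$dense_units %||% 32,
                        epochs = config$lstm$epochs %||% 30,
                        seed = config$seed)
      runs <- config$lstm$runs %||% 3
      out[[paste("dnn", mode, sep = ".")]] <-
        fit_predict_dnn_runs(frames$train, frames$test, spec, runs)
      manifest[[paste("dnn", mode, sep = ".")]] <-
        list(hidden_units = spec$hidden_units, dense_units = spec$dense_units,
             epochs = spec$epochs, runs = runs, seed = spec$seed)
    }
  }
  baseline <- persistence_baseline(ch_te$glucose, horizon)
  list(forecasts = out, baseline = baseline, manifest = manifest)
}

# mean +/- sd aggregation of per-run metric rows (multi-run DNN protocol)
aggregate_runs <- function(rows) {
  num <- c("rmse", "mae", "mcc", "se")
  agg <- rows[1, , drop = FALSE]
  for (col in num) {
    agg[[col]] <- mean(rows[[col]])
    agg[[paste0(col, "_sd")]] <- if (nrow(rows) > 1) sd(rows[[col]]) else NA_real_
  }
  agg
}

#' Run the full benchmark
#'
#' For every (patient x model x input mode x horizon): preprocess, fit,
#' forecast and score; the LSTM is repeated over the configured number of
#' seeded runs and reported as mean and standard deviation per metric.
#' The statistical layer then compares models (Friedman, gated Nemenyi +
#' Holm) per input mode and inputs (exact Wilcoxon) per model. A manifest
#' records every seed and hyperparameter.
#'
#' @param config a [benchmark_config()].
#' @param output_dir optional directory; when given, the metric table,
#'   the p-value tables, the baseline table and the manifest are written
#'   there as CSV/JSON.
#' @return list with `metrics` (one row per patient/model/input/horizon),
#'   `baselines` (persistence rows), `model_comparison` and
#'   `input_comparison` (p-value tables), `reports` (full
#'   [compare_models()] objects) and `manifest`.
#' @export
run_benchmark <- function(config, output_dir = NULL) {
  records <- if (inherits(config$cohort, "simulation_config")) {
    cohort_cfg <- config$cohort
    cohort_cfg$seed <- config$seed
    simulate_cohort(cohort_cfg)
  } else {
    lapply(config$cohort, read_ohio_xml, quiet = TRUE)
  }
  grid_obj <- seg_grid()
  metrics <- list(); baselines <- list()
  manifest <- list(seed = config$seed,
                   package_version = as.character(utils::packageVersion("glucobench")),
                   patients = list())

  for (rec in records) {
    for (horizon in config$horizons) {
      res <- tryCatch(
        forecast_patient(rec, config, horizon),
        error = function(e) stopf("patient %s, horizon %d: %s",
                                  rec$patient_id, horizon,
                                  conditionMessage(e)))
      manifest$patients[[rec$patient_id]][[as.character(horizon)]] <-
        res$manifest
      for (key in names(res$forecasts)) {
        rows <- do.call(rbind, lapply(res$forecasts[[key]], score_forecast,
                                      patient_id = rec$patient_id,
                                      grid = grid_obj,
                                      hypo_threshold = config$hypo_threshold,
                                      hyper_threshold = config$hyper_threshold,
                                      include_imputed = config$include_imputed))
        metrics[[length(metrics) + 1]] <- aggregate_runs(rows)
      }
      baselines[[length(baselines) + 1]] <-
        score_forecast(res$baseline, patient_id = rec$patient_id,
                       grid = grid_obj,
                       hypo_threshold = config$hypo_threshold,
                       hyper_threshold = config$hyper_threshold,
                       include_imputed = config$include_imputed)
    }
  }
  metrics <- do.call(rbind, metrics)
  baselines <- do.call(rbind, baselines)
  rownames(metrics) <- rownames(baselines) <- NULL

  analysis <- analyze_metric_table(metrics, alpha = config$alpha)
  out <- list(metrics = metrics, baselines = baselines,
              model_comparison = analysis$model_comparison,
              input_comparison = analysis$input_comparison,
              reports = analysis$reports, manifest = manifest)
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(metrics, file.path(output_dir, "metrics.csv"),
              row.names = FALSE)
    write.csv(baselines, file.path(output_dir, "baselines.csv"),
              row.names = FALSE)
    if (!is.null(analysis$model_comparison))
      write.csv(analysis$model_comparison,
                file.path(output_dir, "model_comparison.csv"),
                row.names = FALSE)
    if (!is.null(analysis$input_comparison))
      write.csv(analysis$input_comparison,
                file.path(output_dir, "input_comparison.csv"),
                row.names = FALSE)
    jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  out
}

.metric_direction <- c(rmse = "lower", mae = "lower", mcc = "higher",
                       se = "lower")

# pivot a long metric table into a patients x treatments matrix
metric_matrix <- function(metrics, metric, treatment_col) {
  pts <- sort(unique(metrics$patient_id))
  trt <- sort(unique(metrics[[treatment_col]]))
  m <- matrix(NA_real_, length(pts), length(trt),
              dimnames = list(pts, trt))
  for (i in seq_len(nrow(metrics)))
    m[metrics$patient_id[i], metrics[[treatment_col]][i]] <-
      metrics[[metric]][i]
  if (any(is.na(m)))
    stopf("missing cells for %s: %s", metric,
          paste(which(is.na(m), arr.ind = TRUE), collapse = ", "))
  m
}

#' Statistical layer on a per-patient metric table
#'
#' Applies the model-comparison chain (Friedman omnibus; Nemenyi + Holm
#' post-hoc only when the omnibus p-value is below `alpha`) per
#' (horizon, input mode, metric), and the input comparison (exact
#' two-sided drop-zero Wilcoxon signed-rank between univariate and
#' multivariate) per (horizon, model, metric).
#'
#' @param metrics data frame with columns `patient_id`, `model`, `input`,
#'   `horizon` and the metric columns `rmse`, `mae`, `mcc`, `se` (the
#'   study's per-patient table layout). A `cohort` column, when present,
#'   stratifies every analysis.
#' @param alpha significance level.
#' @return list with `model_comparison` and `input_comparison` p-value
#'   tables and `reports` (named list of [compare_models()] objects for
#'   the model comparisons).
#' @export
analyze_metric_table <- function(metrics, alpha = 0.05) {
  metrics$cohort <- metrics$cohort %||% "all"
  metric_names <- intersect(names(.metric_direction), names(metrics))
  model_rows <- list(); input_rows <- list(); reports <- list()

  for (co in unique(metrics$cohort)) for (hz in unique(metrics$horizon)) {
    sub_h <- metrics[metrics$cohort == co & metrics$horizon == hz, ]
    # model comparison per input mode
    for (im in unique(sub_h$input)) {
      sub <- sub_h[sub_h$input == im, ]
      if (length(unique(sub$model)) < 2) next
      for (met in metric_names) {
        m <- metric_matrix(sub, met, "model")
        rep <- compare_models(m, better = .metric_direction[[met]],
                              alpha = alpha)
        key <- paste(co, hz, im, met, sep = ".")
        reports[[key]] <- rep
        model_rows[[key]] <- data.frame(
          cohort = co, horizon = hz, input = im, metric = met,
          friedman_chi2 = rep$friedman_chi2, friedman_p = rep$friedman_p,
          significant = rep$friedman_p < alpha)
      }
    }
    # input comparison per model
    if (all(c("univariate", "multivariate") %in% sub_h$input)) {
      for (md in unique(sub_h$model)) {
        sub <- sub_h[sub_h$model == md, ]
        for (met in metric_names) {
          m <- metric_matrix(sub, met, "input")
          w <- wilcoxon_exact(m[, "univariate"], m[, "multivariate"])
          input_rows[[paste(co, hz, md, met, sep = ".")]] <- data.frame(
            cohort = co, horizon = hz, model = md, metric = met,
            p_value = w$p_value, n_effective = w$n_effective,
            n_zero = w$n_zero, significant = w$p_value < alpha)
        }
      }
    }
  }
  list(model_comparison = if (length(model_rows))
         do.call(rbind, c(model_rows, make.row.names = FALSE)) else NULL,
       input_comparison = if (length(input_rows))
         do.call(rbind, c(input_rows, make.row.names = FALSE)) else NULL,
       reports = reports)
}

#' Published per-patient metric table bundled with the package
#'
#' The per-patient RMSE/MAE/MCC/SE values printed in the source study's
#' evaluation tables for both cohorts, both horizons, three models and
#' both input modes (DNN rows are the printed mean over 10 runs, with the
#' printed standard deviation in the `*_sd` columns). These printed values
#' are the inputs from which the statistical layer of the study can be
#' recomputed without any restricted data.
#'
#' @return data frame with columns `cohort`, `horizon`, `patient_id`,
#'   `model`, `input`, `rmse`, `mae`, `mcc`, `se` and `*_sd` columns.
#' @export
printed_metric_tables <- function() {
  path <- system.file("extdata", "printed_metric_tables.csv",
                      package = "glucobench")
  if (path == "") stopf("bundled metric table not found")
  out <- read.csv(path, stringsAsFactors = FALSE)
  out$patient_id <- as.character(out$patient_id)
  out
}

#' Recompute the statistical layer from a published metric table
#'
#' Runs the Friedman (model-comparison) or Wilcoxon (input-comparison)
#' layer directly on a per-patient metric table — printed study values or
#' any table in the same layout — without running any model.
#'
#' @param table a metric table data frame (default the bundled
#'   [printed_metric_tables()]), or a path to a CSV in that layout.
#' @param analysis `"friedman"` or `"wilcoxon"`.
#' @param alpha significance level.
#' @return the corresponding p-value table from [analyze_metric_table()].
#' @export
replay_printed_tables <- function(table = printed_metric_tables(),
                                  analysis = c("friedman", "wilcoxon"),
                                  alpha = 0.05) {
  analysis <- match.arg(analysis)
  if (is.character(table)) table <- read.csv(table, stringsAsFactors = FALSE)
  table$patient_id <- as.character(table$patient_id)
  res <- analyze_metric_table(table, alpha = alpha)
  if (analysis == "friedman") res$model_comparison else res$input_comparison
}

#' Cohort-average metric rows
#'
#' Arithmetic mean of the per-patient metric values for each
#' (cohort, horizon, model, input) cell — the "Avg" rows of the study's
#' evaluation tables.
#'
#' @param metrics a metric table (see [analyze_metric_table()]).
#' @return data frame of averages.
#' @export
cohort_averages <- function(metrics) {
  metrics$cohort <- metrics$cohort %||% "all"
  agg <- aggregate(metrics[c("rmse", "mae", "mcc", "se")],
                   by = metrics[c("cohort", "horizon", "model", "input")],
                   FUN = mean)
  agg[order(agg$cohort, agg$horizon, agg$model, agg$input), ]
}
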