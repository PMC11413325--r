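# Shared fixtures: tiny simulated records and preprocessed channel sets,
# built once per test run.

small_config <- function(...) {
  simulation_config(n_patients = 2, duration_days = 14, test_days = 3,
                    seed = 1, ...)
}

# memoised preprocessed patient (train/test channel lists)
fixture_env <- new.env()

small_channels <- function() {
  if (is.null(fixture_env$channels)) {
    cfg <- small_config()
    rec <- inject_gaps(simulate_patient(cfg, 0), cfg)
    parts <- split_train_test(rec)
    fixture_env$channels <- list(
      train = preprocess_record(parts$train, "train"),
      test = preprocess_record(parts$test, "test"))
  }
  fixture_env$channels
}

# regular series data frame on a 5-min grid from a numeric vector
series_df <- function(values, start = as.POSIXct("2024-01-01", tz = "UTC"),
                      by_minutes = 5, missing = NULL) {
  n <- length(values)
  data.frame(time = start + (seq_len(n) - 1) * by_minutes * 60,
             value = values,
             missing = missing %||% is.na(values))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force exact two-sided Wilcoxon signed-rank p by full 2^n
# enumeration of sign assignments (independent oracle)
wilcoxon_bruteforce <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- signs %*% r
  p_le <- mean(w_all <= w_obs + 1e-9)
  p_ge <- mean(w_all >= w_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}
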