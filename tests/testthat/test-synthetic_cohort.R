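test_that("glucose stays at basal with no events and no noise", {
  cfg <- simulation_config(n_patients = 1, duration_days = 3, test_days = 1,
                           meal_rate = 0, noise_sd = 0, activity_effect = 0,
                           gap_rate = 0, seed = 1)
  rec <- simulate_patient(cfg, 0)
  expect_true(all(abs(rec$glucose$value - cfg$basal_glucose) < 1e-9))
})

test_that("a single meal raises glucose then decays back to basal", {
  cfg <- simulation_config(n_patients = 1, duration_days = 2, test_days = 0,
                           meal_rate = 0, noise_sd = 0, activity_effect = 0,
                           gap_rate = 0, seed = 1)
  rec <- simulate_patient(cfg, 0)
  # inject one 50 g meal at hour 2, no bolus, and replay the dynamics
  rec$carb <- data.frame(time = rec$glucose$time[1] + 2 * 3600, value = 50)
  rec$bolus <- rec$bolus[0, ]
  km <- glucobench:::impulse_kernel(cfg$meal_absorption_peak, 5)
  g <- rep(cfg$basal_glucose, nrow(rec$glucose))
  meal_in <- numeric(length(g))
  i0 <- 2 * 12 + 1
  idx <- i0 + seq_along(km) - 1
  meal_in[idx] <- 50 * cfg$carb_effect * km
  for (t in seq_len(length(g) - 1))
    g[t + 1] <- min(400, max(40, g[t] +
      cfg$mean_reversion_rate * (cfg$basal_glucose - g[t]) + meal_in[t]))
  within_3h <- i0:(i0 + 36)
  expect_gt(max(g[within_3h]), cfg$basal_glucose)
  at_12h <- i0 + 120
  expect_lt(abs(g[at_12h] - cfg$basal_glucose), 5)
})

test_that("simulation is deterministic and patients differ", {
  cfg <- simulation_config(n_patients = 2, duration_days = 5, test_days = 1,
                           seed = 7)
  a <- simulate_patient(cfg, 0)
  b <- simulate_patient(cfg, 0)
  expect_identical(a, b)
  other <- simulate_patient(cfg, 1)
  expect_false(identical(a$glucose$value, other$glucose$value))
})

test_that("generated records respect physical bounds and channel structure", {
  cfg <- simulation_config(n_patients = 1, duration_days = 7, test_days = 2,
                           activity_mode = "accel_magnitude_1min",
                           noise_sd = 8, seed = 3)
  rec <- simulate_patient(cfg, 0)
  expect_true(all(rec$glucose$value >= 40 & rec$glucose$value <= 400))
  expect_true(all(rec$carb$value >= 0))
  expect_true(all(rec$bolus$value >= 0))
  # 1-min activity has 5x the samples of the 5-min glucose grid
  expect_equal(nrow(rec$activity), 5 * nrow(rec$glucose))
})

test_that("gap injection matches its Poisson rate and never removes rows", {
  cfg <- simulation_config(n_patients = 1, duration_days = 56, test_days = 10,
                           gap_rate = 2, gap_mean = 20, gap_sd = 5, seed = 3)
  rec <- simulate_patient(cfg, 0)
  gapped <- inject_gaps(rec, cfg)
  expect_equal(nrow(gapped$glucose), nrow(rec$glucose))
  # 99% band for Poisson(112): qpois(c(.005,.995), 112)
  n_gaps <- gap_count(gapped)
  expect_gte(n_gaps, qpois(0.005, 112))
  expect_lte(n_gaps, qpois(0.995, 112))
  expect_equal(missing_fraction(gapped),
               sum(gapped$glucose$missing) / nrow(gapped$glucose))
  # rate zero leaves the record untouched
  cfg0 <- simulation_config(gap_rate = 0)
  expect_identical(inject_gaps(rec, cfg0), rec)
  # configurations implying >50% missingness are rejected
  cfg_bad <- simulation_config(gap_rate = 48, gap_mean = 20)
  expect_error(inject_gaps(rec, cfg_bad), "missingness")
})

test_that("train/test split is half-open with the boundary on the test side", {
  cfg <- simulation_config(n_patients = 1, duration_days = 56, test_days = 10,
                           seed = 1)
  rec <- simulate_patient(cfg, 0)
  parts <- split_train_test(rec)
  expect_equal(nrow(parts$train$glucose), 46 * 288)
  expect_equal(nrow(parts$test$glucose), 10 * 288)
  expect_equal(parts$test$glucose$time[1], rec$split_time)
  expect_true(max(parts$train$glucose$time) < rec$split_time)
  # test_days = 0 gives an empty test view
  parts0 <- split_train_test(rec, test_days = 0)
  expect_equal(nrow(parts0$test$glucose), 0)
  expect_equal(nrow(parts0$train$glucose), nrow(rec$glucose))
  expect_error(split_train_test(rec, test_days = 100), "shorter")
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(duration_days = 5, test_days = 10), "test_days")
  expect_error(simulation_config(sample_interval = 7), "divide")
  expect_error(simulation_config(meal_rate = -1), "non-negative")
  expect_error(simulate_patient(simulation_config(n_patients = 2), 5),
               "patient_index")
})
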