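fc_from_residuals <- function(ref, pred, imputed = NULL) {
  n <- length(ref)
  forecast_series(
    target_times = as.POSIXct("2024-01-01", tz = "UTC") + (1:n) * 300,
    predicted = pred, reference = ref, horizon = 30,
    reference_imputed = imputed)
}

test_that("RMSE and MAE reproduce their worked examples", {
  fc <- fc_from_residuals(c(103, 104), c(100, 100))   # residuals 3, 4
  expect_equal(rmse(fc), sqrt(12.5))
  expect_equal(mae(fc), 3.5)
  perfect <- fc_from_residuals(c(100, 150), c(100, 150))
  expect_equal(rmse(perfect), 0)
  expect_equal(mae(perfect), 0)
  # constant residuals collapse the two metrics
  const <- fc_from_residuals(c(105, 115), c(100, 110))
  expect_equal(rmse(const), mae(const))
  # sign flips leave MAE unchanged
  flip <- fc_from_residuals(c(97, 96), c(100, 100))
  expect_equal(mae(flip), 3.5)
})

test_that("RMSE dominates MAE on random forecasts", {
  set.seed(8)
  for (i in 1:20) {
    fc <- fc_from_residuals(runif(30, 60, 250), runif(30, 60, 250))
    expect_gte(rmse(fc), mae(fc))
  }
})

test_that("the scoring mask excludes imputed reference points", {
  fc <- fc_from_residuals(c(100, 200, 100), c(100, 100, 100),
                          imputed = c(FALSE, TRUE, FALSE))
  expect_equal(rmse(fc), 0)
  expect_equal(rmse(fc, include_imputed = TRUE), sqrt(10000 / 3))
  all_imp <- fc_from_residuals(c(1, 2) + 100, c(100, 100),
                               imputed = c(TRUE, TRUE))
  expect_error(rmse(all_imp), "no scored pairs")
})

test_that("glycaemic state classification uses strict thresholds", {
  expect_true(classify_glycaemic_state(65))
  expect_false(classify_glycaemic_state(100))
  expect_false(classify_glycaemic_state(70))     # boundary is normoglycaemic
  expect_false(classify_glycaemic_state(180))
  expect_true(classify_glycaemic_state(180.5))
  expect_error(classify_glycaemic_state(100, 180, 70), "below")
})

test_that("event MCC matches the closed formula and its conventions", {
  # TP=4, TN=3, FP=2, FN=1 -> (4*3 - 2*1) / sqrt(6*5*5*4) = 10 / sqrt(600)
  ref <- c(rep(60, 4), rep(100, 3), rep(100, 2), rep(60, 1))
  prd <- c(rep(60, 4), rep(100, 3), rep(60, 2), rep(100, 1))
  expect_equal(mcc_events(fc_from_residuals(ref, prd)), 10 / sqrt(600))
  # perfect agreement with both classes present
  both <- fc_from_residuals(c(60, 100), c(65, 110))
  expect_equal(mcc_events(both), 1)
  # all-normo predictions against a mixed reference: zero by convention
  degen <- fc_from_residuals(c(60, 100, 120), c(100, 110, 120))
  expect_equal(mcc_events(degen), 0)
  # symmetric under simultaneous class swap, bounded
  inv <- fc_from_residuals(prd, ref)
  expect_equal(mcc_events(inv), mcc_events(fc_from_residuals(ref, prd)))
  expect_lte(abs(mcc_events(inv)), 1)
})

test_that("the synthetic SEG surface satisfies its structural invariants", {
  grid <- seg_grid()                       # validation runs at construction
  expect_equal(seg_risk(100, 100, grid), 0)
  expect_equal(seg_risk(250.0, 110.0, grid), grid$risk[251, 111])  # node identity
  # cell-centre query equals the mean of the four corner risks
  centre <- seg_risk(100.5, 200.5, grid)
  corners <- grid$risk[101:102, 201:202]
  expect_equal(centre, mean(corners))
  # continuity across shared cell edges
  expect_equal(seg_risk(100, 199.9999, grid), seg_risk(100, 200, grid),
               tolerance = 1e-3)
  # clamping: out-of-range queries use the boundary
  expect_equal(seg_risk(700, 700, grid), 0)
  # dangerous quadrants weigh more: a +100 overprediction is riskier during
  # hypoglycaemia than the same excursion at a normal reference
  expect_gt(seg_risk(50, 150, grid), seg_risk(150, 250, grid))
  # and underprediction is riskier during hyperglycaemia than normality
  expect_gt(seg_risk(300, 200, grid), seg_risk(200, 100 + 33, grid))
})

test_that("surveillance error is a mean of per-pair risks and zero when perfect", {
  grid <- seg_grid()
  perfect <- fc_from_residuals(c(80, 120, 300), c(80, 120, 300))
  expect_equal(surveillance_error(perfect, grid), 0)
  two <- fc_from_residuals(c(60, 240), c(90, 180))
  expect_equal(surveillance_error(two, grid),
               mean(seg_risk(c(60, 240), c(90, 180), grid)))
})

test_that("surveillance error grows with forecast noise", {
  grid <- seg_grid()
  ref <- seq(60, 300, length.out = 200)
  sds <- seq(0, 50, by = 10)
  ok <- 0; total <- 0
  for (s in 1:20) {
    set.seed(s)
    se <- vapply(sds, function(sd0)
      surveillance_error(fc_from_residuals(ref, ref + rnorm(200, 0, sd0)),
                         grid), 0)
    d <- diff(se)
    ok <- ok + sum(d >= 0); total <- total + length(d)
  }
  expect_gte(ok / total, 0.95)
})

test_that("the SEG plot writes a file with one point per forecast pair", {
  fc <- fc_from_residuals(c(80, 150, 250), c(90, 140, 260))
  path <- file.path(tempdir(), "seg_test.png")
  gg <- plot_seg(fc, file = path)
  expect_true(file.exists(path))
  expect_equal(nrow(gg$layers[[2]]$data), 3)
  unlink(path)
})

test_that("score_forecast assembles a complete metric row", {
  fc <- fc_from_residuals(c(60, 100, 200), c(65, 102, 190))
  row <- score_forecast(fc, patient_id = "p1")
  expect_equal(row$n, 3)
  expect_named(row, c("patient_id", "model", "input", "horizon",
                      "rmse", "mae", "mcc", "se", "n"))
  expect_gte(row$rmse, row$mae)
})
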