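test_that("train-mode imputation interpolates between neighbours", {
  s <- series_df(c(100, NA, 120), by_minutes = 5)
  out <- impute_series(s, "train")
  expect_equal(out$value, c(100, 110, 120))
  expect_equal(out$imputed, c(FALSE, TRUE, FALSE))
})

test_that("test-mode imputation extrapolates causally from the last two points", {
  s <- series_df(c(100, 110, NA, NA), by_minutes = 5)
  out <- impute_series(s, "test")
  expect_equal(out$value, c(100, 110, 120, 130))
  # causality: changing values after the gap never changes the fill
  s2 <- series_df(c(100, 110, NA, NA, 55, 300), by_minutes = 5)
  s3 <- s2; s3$value[5:6] <- c(250, 80)
  expect_equal(impute_series(s2, "test")$value[3:4],
               impute_series(s3, "test")$value[3:4])
})

test_that("imputation is an identity on complete series and idempotent", {
  s <- series_df(c(95, 100, 104, 99))
  out <- impute_series(s, "train")
  expect_equal(out$value, s$value)
  expect_false(any(out$imputed))
  gap <- series_df(c(95, NA, 104, 99))
  once <- impute_series(gap, "train")
  twice <- impute_series(once, "train")
  expect_equal(once$value, twice$value)
  expect_error(impute_series(series_df(c(NA, 100, NA)), "train"), "2 observed")
})

test_that("event zero-filling bins to the nearest grid point and sums collisions", {
  grid <- as.POSIXct("2024-01-01 12:00:00", tz = "UTC") + (0:5) * 300
  none <- zero_fill_events(data.frame(time = grid[0], value = numeric(0)), grid)
  expect_equal(none$value, rep(0, 6))
  meal <- data.frame(time = as.POSIXct("2024-01-01 12:03:00", tz = "UTC"),
                     value = 45)
  out <- zero_fill_events(meal, grid)
  expect_equal(out$value, c(0, 45, 0, 0, 0, 0))     # 12:03 -> 12:05 bin
  two <- data.frame(time = rep(as.POSIXct("2024-01-01 12:10:30", tz = "UTC"), 2),
                    value = c(2, 3))
  expect_equal(zero_fill_events(two, grid)$value[3], 5)
})

test_that("activity alignment keeps the nearest sample and drops the rest", {
  start <- as.POSIXct("2024-01-01", tz = "UTC")
  act <- data.frame(time = start + (0:4) * 60, value = 1:5)   # 1-min samples
  out <- align_activity(act, start)                            # one glucose point
  expect_equal(nrow(out), 1)
  expect_equal(out$value, 1)
  # already-aligned 5-min series passes through unchanged
  act5 <- data.frame(time = start + (0:3) * 300, value = c(60, 62, 64, 66))
  expect_equal(align_activity(act5, act5$time)$value, act5$value)
  # tie (two samples equally near) resolves to the earlier sample
  tie <- data.frame(time = start + c(-30, 30), value = c(10, 20))
  expect_equal(align_activity(tie, start)$value, 10)
  far <- data.frame(time = start + 86400 * 10, value = 1)
  expect_error(align_activity(far, start), "overlap")
})

test_that("boundary trimming restricts channels to the common span", {
  start <- as.POSIXct("2024-01-01", tz = "UTC")
  glucose <- data.frame(time = start + (0:23) * 300, value = 100)
  activity <- data.frame(time = start + (12:23) * 300, value = 70)  # 1 h later
  out <- trim_boundaries(list(glucose = glucose, activity = activity))
  expect_equal(nrow(out$glucose), 12)                # first 12 points dropped
  expect_equal(out$glucose$time[1], activity$time[1])
  # nested spans intersect to the innermost one
  mid <- data.frame(time = start + (14:20) * 300, value = 1)
  out3 <- trim_boundaries(list(a = glucose, b = activity, c = mid))
  expect_equal(nrow(out3$a), 7)
  same <- trim_boundaries(list(g = glucose))
  expect_equal(same$g, glucose)
  late <- data.frame(time = start + 86400, value = 1)
  expect_error(trim_boundaries(list(a = glucose, b = late)), "empty")
})

test_that("reframing produces the documented window count and shapes", {
  ch <- list(glucose = series_df(as.numeric(1:20)),
             carb = series_df(rep(0, 20)),
             bolus = series_df(rep(0, 20)),
             activity = series_df(rep(70, 20)))
  fr <- reframe(ch, 12, 6, "univariate")
  expect_equal(length(fr$inputs), 3)                  # 20 - 12 - 6 + 1
  expect_equal(dim(fr$inputs[[1]]), c(12, 1))
  frm <- reframe(ch, 12, 6, "multivariate")
  expect_equal(dim(frm$inputs[[1]]), c(12, 4))
  expect_equal(frm$channels, c("glucose", "carb", "bolus", "activity"))
  # first target vector equals raw values at positions L..L+H-1
  expect_equal(fr$targets[[1]], as.numeric(13:18))
  expect_error(reframe(ch, 18, 6, "univariate"), "too short")
})

test_that("reframed targets reconstruct the original series over their span", {
  ch <- list(glucose = series_df(sin(1:40) * 10 + 100))
  fr <- reframe(ch, 8, 4, "univariate")
  rebuilt <- c(fr$targets[[1]],
               vapply(fr$targets[-1], function(t) t[fr$horizon], 0))
  expect_equal(rebuilt, ch$glucose$value[9:40])
})
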