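make_ramp_frames <- function(n = 200, L = 6, H = 3) {
  # periodic triangular wave: noiseless linear ramp segments whose
  # validation span stays inside the training value range
  x <- (1:n) %% 50
  vals <- 80 + pmin(x, 50 - x)
  ch <- list(glucose = series_df(vals))
  fr <- reframe(ch, L, H, "univariate")
  k <- length(fr$inputs)
  list(train = glucobench:::frame_subset(fr, 1:(k - 40)),
       test = glucobench:::frame_subset(fr, (k - 39):k))
}

test_that("grid search honours its contract and search spaces", {
  fr <- make_ramp_frames()
  # singleton spaces: returned untouched, no search
  single <- grid_search_svr(fr$train, gamma_space = 2, C_space = 5,
                            epsilon_space = 0.3)
  expect_equal(unlist(single[c("gamma", "C", "epsilon")]),
               c(gamma = 2, C = 5, epsilon = 0.3))
  gs <- c(0.1, 1); cs <- c(0.1, 1); es <- c(0.01, 0.1)
  pars <- grid_search_svr(fr$train, gs, cs, es)
  expect_true(pars$gamma %in% gs && pars$C %in% cs && pars$epsilon %in% es)
  expect_error(grid_search_svr(fr$train, numeric(0), cs, es), "non-empty")
})

test_that("noiseless ramp segments are fit to within the epsilon tube", {
  fr <- make_ramp_frames()
  pars <- grid_search_svr(fr$train, gamma_space = c(1, 10),
                          C_space = c(1, 10), epsilon_space = 0.01)
  # epsilon 0.01 in the scaled [0,1] space is 0.25 mg/dL on this signal;
  # allow a small interpolation tolerance on top
  expect_lte(pars$rmse, 0.25 + 1)
})

test_that("constant training targets predict within epsilon of the constant", {
  ch <- list(glucose = series_df(rep(120, 60)))
  fr <- reframe(ch, 6, 3, "univariate")
  k <- length(fr$inputs)
  tr <- glucobench:::frame_subset(fr, 1:(k - 10))
  te <- glucobench:::frame_subset(fr, (k - 9):k)
  fc <- fit_predict_tml(tr, te, list(gamma = 1, C = 1, epsilon = 0.1))
  # scaled space degenerates to 0, so predictions sit within the tube
  expect_true(all(abs(fc$predicted - 120) < 1))
})

test_that("all-zero exogenous channels leave SVR predictions unchanged", {
  vals <- 100 + 20 * sin((1:150) / 7)
  ch_uni <- list(glucose = series_df(vals))
  ch_multi <- list(glucose = series_df(vals), carb = series_df(rep(0, 150)),
                   bolus = series_df(rep(0, 150)),
                   activity = series_df(rep(0, 150)))
  split_fr <- function(fr) {
    k <- length(fr$inputs)
    list(tr = glucobench:::frame_subset(fr, 1:(k - 20)),
         te = glucobench:::frame_subset(fr, (k - 19):k))
  }
  u <- split_fr(reframe(ch_uni, 8, 3, "univariate"))
  m <- split_fr(reframe(ch_multi, 8, 3, "multivariate"))
  pars <- list(gamma = 1, C = 1, epsilon = 0.01)
  fu <- fit_predict_tml(u$tr, u$te, pars)
  fm <- fit_predict_tml(m$tr, m$te, pars)
  # constant (zero) features do not move the RBF kernel distances
  expect_equal(fu$predicted, fm$predicted, tolerance = 1e-6)
})

test_that("mismatched frame shapes are rejected", {
  fr <- make_ramp_frames()
  other <- make_ramp_frames(L = 4)
  expect_error(fit_predict_tml(fr$train, other$test,
                               list(gamma = 1, C = 1, epsilon = 0.1)),
               "share")
})

test_that("SVR beats persistence at 30 min on a synthetic patient", {
  ch <- small_channels()
  frames <- glucobench:::build_frames(ch$train, ch$test, 12, 6, "univariate")
  pars <- grid_search_svr(frames$train, gamma_space = c(1, 10),
                          C_space = c(0.1, 1), epsilon_space = 0.01)
  fc <- fit_predict_tml(frames$train, frames$test, pars)
  base <- persistence_baseline(ch$test$glucose, 30)
  expect_identical(fc$target_times, base$target_times)
  expect_lt(rmse(fc), rmse(base))
})
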