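# Traditional-machine-learning forecaster: epsilon-insensitive support
# vector regression with a radial basis kernel on flattened sliding-window
# features, one single-output model per prediction horizon.

# split a supervised frame into fit/validation parts, time-ordered
frame_validation_split <- function(frame, validation_fraction = 0.2) {
  n <- length(frame$inputs)
  n_val <- floor(n * validation_fraction)
  if (n_val < 1) stopf("validation split is empty")
  list(fit_idx = seq_len(n - n_val), val_idx = (n - n_val + 1):n)
}

# min-max scale a design matrix / target using training statistics
scale_design <- function(X, y, scalers = NULL) {
  if (is.null(scalers)) {
    scalers <- list(x = apply(X, 2, fit_minmax), y = fit_minmax(y))
  }
  Xs <- X
  for (j in seq_len(ncol(X))) Xs[, j] <- apply_minmax(X[, j], scalers$x[[j]])
  list(X = Xs, y = apply_minmax(y, scalers$y), scalers = scalers)
}

#' Grid search for SVR hyperparameters
#'
#' Fits an RBF-kernel support vector regressor for every
#' `(gamma, C, epsilon)` triple on the time-ordered fit portion of the
#' training frame and returns the triple minimising validation RMSE of the
#' horizon-step prediction. Ties are broken by smaller `C`, then smaller
#' `gamma` (preferring smoother models). The default spaces are the study
#' spaces; all three are configuration.
#'
#' @param frame a training [reframe()] frame.
#' @param gamma_space,C_space,epsilon_space finite search spaces.
#' @param validation_fraction final fraction of the training windows used
#'   as the time-ordered validation set.
#' @return list with `gamma`, `C`, `epsilon` and the attained `rmse`.
#' @export
grid_search_svr <- function(frame,
                            gamma_space = c(0.1, 1, 10, 100),
                            C_space = c(0.001, 0.01, 0.1, 1),
                            epsilon_space = c(0.01, 0.1, 1, 10),
                            validation_fraction = 0.2) {
  if (!length(gamma_space) || !length(C_space) || !length(epsilon_space))
    stopf("search spaces must be non-empty")
  des <- frame_design(frame)
  grid <- expand.grid(gamma = gamma_space, C = C_space,
                      epsilon = epsilon_space)
  if (nrow(grid) == 1)
    return(list(gamma = grid$gamma, C = grid$C, epsilon = grid$epsilon,
                rmse = NA_real_))
  sp <- frame_validation_split(frame, validation_fraction)
  sc <- scale_design(des$X[sp$fit_idx, , drop = FALSE], des$y[sp$fit_idx])
  val <- scale_design(des$X[sp$val_idx, , drop = FALSE], des$y[sp$val_idx],
                      sc$scalers)
  val_rmse <- vapply(seq_len(nrow(grid)), function(i) {
    pred_s <- svr_fit_predict(sc$X, sc$y, val$X,
                              gamma = grid$gamma[i], C = grid$C[i],
                              epsilon = grid$epsilon[i])
    pred <- invert_minmax(pred_s, sc$scalers$y)
    sqrt(mean((des$y[sp$val_idx] - pred)^2))
  }, 0)
  best <- order(val_rmse, grid$C, grid$gamma)[1]
  list(gamma = grid$gamma[best], C = grid$C[best],
       epsilon = grid$epsilon[best], rmse = val_rmse[best])
}

#' Fit and predict with the SVR forecaster
#'
#' Trains one single-output RBF-kernel support vector regressor predicting
#' glucose at the final horizon step from the flattened `L x C` history
#' window (per-patient min-max scaling fitted on training data, inverted
#' before scoring), then predicts at every test target time.
#'
#' @param frame_train,frame_test matching [reframe()] frames (same
#'   history length, horizon and channels).
#' @param params list with `gamma`, `C`, `epsilon` (e.g. from
#'   [grid_search_svr()]).
#' @return a [forecast_series()].
#' @export
fit_predict_tml <- function(frame_train, frame_test, params) {
  if (frame_train$history_length != frame_test$history_length ||
      frame_train$horizon != frame_test$horizon ||
      !identical(frame_train$channels, frame_test$channels))
    stopf("train and test frames must share L, H and channels")
  tr <- frame_design(frame_train)
  te <- frame_design(frame_test)
  sc <- scale_design(tr$X, tr$y)
  tes <- scale_design(te$X, te$y, sc$scalers)
  pred_s <- svr_fit_predict(sc$X, sc$y, tes$X, gamma = params$gamma,
                            C = params$C, epsilon = params$epsilon)
  pred <- invert_minmax(pred_s, sc$scalers$y)
  forecast_series(
    target_times = frame_test$target_times,
    predicted = as.numeric(pred),
    reference = te$y,
    horizon = frame_test$horizon * minutes_per_step(frame_test),
    model = "tml",
    input_mode = frame_test$mode,
    reference_imputed = frame_test$target_imputed)
}

# RBF-SVR fit + predict with a guard for the degenerate case where every
# training target sits inside the epsilon tube (no support vectors): the
# model then predicts the constant training mean
svr_fit_predict <- function(X, y, X_new, gamma, C, epsilon) {
  if (sd(y) < 1e-12) return(rep(y[1], nrow(X_new)))
  m <- tryCatch(
    e1071::svm(X, y, type = "eps-regression", kernel = "radial",
               gamma = gamma, cost = C, epsilon = epsilon, scale = FALSE),
    error = function(e) {
      if (grepl("empty", conditionMessage(e), ignore.case = TRUE)) NULL
      else stop(e)
    })
  if (is.null(m) || m$tot.nSV == 0) return(rep(mean(y), nrow(X_new)))
  as.numeric(predict(m, X_new))
}

# grid spacing of a frame in minutes (from consecutive target times)
minutes_per_step <- function(frame) {
  if (length(frame$target_times) < 2) return(5)
  as.numeric(frame$target_times[2] - frame$target_times[1], units = "mins")
}
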