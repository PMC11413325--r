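#' Select an ARIMA order by information-criterion search
#'
#' Fits `arima(p, d, q)` for every `(p, q)` pair on a grid from 0 to
#' `search_max` and returns the order minimising the selection criterion
#' (AIC by default). Ties are broken toward smaller `p + q`, then smaller
#' `p`. The differencing order `d` comes from the stationarity gate
#' ([determine_d()]) and is not searched.
#'
#' @param train numeric glucose training series.
#' @param d differencing order.
#' @param search_max largest AR and MA order searched (the full study range
#'   is 0..36; small caps keep the search tractable).
#' @param criterion `"aic"` (default) or `"bic"`.
#' @param xreg optional exogenous regressor matrix (ARIMAX search).
#' @return list with `p`, `d`, `q` and the attained `criterion` value.
#' @export
select_arima_order <- function(train, d, search_max = 4,
                               criterion = c("aic", "bic"), xreg = NULL) {
  criterion <- match.arg(criterion)
  if (search_max < 0) stopf("search_max must be non-negative")
  if (search_max == 0)
    return(list(p = 0L, d = as.integer(d), q = 0L, criterion = NA_real_))
  grid <- expand.grid(p = 0:search_max, q = 0:search_max)
  score <- rep(NA_real_, nrow(grid))
  failures <- character(0)
  for (i in seq_len(nrow(grid))) {
    fit <- tryCatch(
      arima(train, order = c(grid$p[i], d, grid$q[i]), xreg = xreg,
            method = "CSS-ML"),
      error = function(e) e)
    if (inherits(fit, "error")) {
      failures <- c(failures, sprintf("(%d,%d,%d): %s", grid$p[i], d,
                                      grid$q[i], conditionMessage(fit)))
      next
    }
    score[i] <- if (criterion == "aic") fit$aic else
      fit$aic + (log(length(train)) - 2) * (grid$p[i] + grid$q[i] + 1)
  }
  if (all(is.na(score)))
    stopf("all candidate ARIMA fits failed:\n%s",
          paste(failures, collapse = "\n"))
  ord <- order(score, grid$p + grid$q, grid$p)   # NA scores sort last
  best <- ord[1]
  list(p = as.integer(grid$p[best]), d = as.integer(d),
       q = as.integer(grid$q[best]), criterion = score[best])
}

# conditional-sum-of-squares innovations of an ARMA(p, q) series:
# e_t = z_t - sum(phi_i z_{t-i}) - sum(theta_j e_{t-j}), missing terms = 0
innovations_css <- function(z, phi, theta) {
  n <- length(z); p <- length(phi); q <- length(theta)
  e <- numeric(n)
  for (t in seq_len(n)) {
    ar <- 0
    if (p) for (i in seq_len(min(p, t - 1))) ar <- ar + phi[i] * z[t - i]
    ma <- 0
    if (q) for (j in seq_len(min(q, t - 1))) ma <- ma + theta[j] * e[t - j]
    e[t] <- z[t] - ar - ma
  }
  e
}

# h-step-ahead ARMA point forecasts from history z[1..t] and innovations
# e[1..t]: future innovations are zero, known values feed the recursion
arma_multistep <- function(z, e, phi, theta, h) {
  p <- length(phi); q <- length(theta); t <- length(z)
  zhat <- numeric(h)
  zval <- function(s) if (s <= t) z[s] else zhat[s - t]
  for (j in seq_len(h)) {
    acc <- 0
    if (p) for (i in seq_len(p)) {
      s <- t + j - i
      if (s >= 1) acc <- acc + phi[i] * zval(s)
    }
    if (q) for (m in seq_len(q)) {
      s <- t + j - m
      if (s >= 1 && s <= t) acc <- acc + theta[m] * e[s]
    }
    zhat[j] <- acc
  }
  zhat
}

# undo d rounds of differencing on an h-step forecast of the d-th
# difference, given the level history u[1..t]
integrate_forecast <- function(zhat, u, d) {
  if (d == 0) return(zhat)
  lvl <- zhat
  for (l in seq_len(d)) {
    hist_d <- if (d - l > 0) diff(u, differences = d - l) else u
    lvl <- tail(hist_d, 1) + cumsum(lvl)
  }
  lvl
}

#' Fit and rolling-forecast an ARIMA/ARIMAX model
#'
#' Fits the model on the training glucose series (with carb, bolus and
#' activity as exogenous regressors in multivariate mode), then produces,
#' for every test origin, the H-step-ahead glucose forecast from the model
#' state updated with all data up to that origin (a rolling-origin
#' forecast; coefficients are not re-estimated). Exogenous covariates over
#' the forecast window use their recorded values, as carb and bolus are
#' known inputs in deployment. Innovations along the test span come from a
#' conditional-sum-of-squares filter pass with the fitted coefficients.
#' A non-invertible or explosive fit is refit as `(0, d, 0)` with a
#' warning.
#'
#' @param train,test preprocessed channel lists from [preprocess_record()]
#'   (each holding aligned `glucose`, `carb`, `bolus`, `activity`).
#' @param order list/vector with elements `p`, `d`, `q`.
#' @param horizon prediction horizon in minutes (30 or 60).
#' @param input_mode `"univariate"` (ARIMA) or `"multivariate"` (ARIMAX).
#' @return a [forecast_series()] on the same target grid as
#'   [persistence_baseline()] applied to the test glucose series.
#' @export
fit_predict_ctf <- function(train, test, order, horizon,
                            input_mode = c("univariate", "multivariate")) {
  input_mode <- match.arg(input_mode)
  p <- order$p %||% order[[1]]; d <- order$d %||% order[[2]]
  q <- order$q %||% order[[3]]
  step <- as.numeric(train$glucose$time[2] - train$glucose$time[1],
                     units = "mins")
  h <- horizon / step
  if (h != round(h)) stopf("horizon must be a multiple of the grid spacing")

  y_tr <- train$glucose$value
  y_te <- test$glucose$value
  n_tr <- length(y_tr); n_te <- length(y_te)
  if (n_te <= h) stopf("test series shorter than the horizon")

  xreg_tr <- xreg_te <- NULL
  if (input_mode == "multivariate") {
    xreg_tr <- cbind(carb = train$carb$value, bolus = train$bolus$value,
                     activity = train$activity$value)
    xreg_te <- cbind(carb = test$carb$value, bolus = test$bolus$value,
                     activity = test$activity$value)
  }

  fit <- tryCatch(
    arima(y_tr, order = c(p, d, q), xreg = xreg_tr, method = "CSS-ML"),
    error = function(e) e)
  if (inherits(fit, "error") ||
      (length(fit$model$phi) && any(abs(polyroot(c(1, -fit$model$phi))) < 1.001))) {
    warnf("ARIMA(%d,%d,%d) fit failed or is explosive; falling back to (0,%d,0)",
          p, d, q, d)
    p <- q <- 0L
    fit <- arima(y_tr, order = c(0, d, 0), xreg = xreg_tr, method = "CSS-ML")
  }

  cf <- coef(fit)
  phi <- unname(cf[grep("^ar[0-9]+$", names(cf))])
  theta <- unname(cf[grep("^ma[0-9]+$", names(cf))])
  mu <- if ("intercept" %in% names(cf)) unname(cf["intercept"]) else 0
  beta <- cf[setdiff(names(cf),
                     c(grep("^(ar|ma)[0-9]+$", names(cf), value = TRUE),
                       "intercept"))]

  y_full <- c(y_tr, y_te)
  reg_part <- if (length(beta))
    as.numeric(rbind(xreg_tr, xreg_te) %*% beta) else 0
  u <- y_full - mu - reg_part                 # ARMA part on the level scale
  z <- if (d > 0) diff(u, differences = d) else u
  e <- innovations_css(z, phi, theta)

  origins <- seq_len(n_te - h)                # test indices acting as origins
  pred <- numeric(length(origins))
  for (i in seq_along(origins)) {
    t_full <- n_tr + origins[i]               # origin index in the full series
    t_z <- t_full - d
    zhat <- arma_multistep(z[seq_len(t_z)], e[seq_len(t_z)], phi, theta, h)
    lvl <- integrate_forecast(zhat, u[seq_len(t_full)], d)
    pred[i] <- lvl[h] + mu +
      (if (length(beta)) as.numeric(xreg_te[origins[i] + h, ] %*% beta) else 0)
  }

  idx <- origins + h
  forecast_series(
    target_times = test$glucose$time[idx],
    predicted = pred,
    reference = y_te[idx],
    horizon = horizon, model = "ctf", input_mode = input_mode,
    reference_imputed = (test$glucose$imputed %||% rep(FALSE, n_te))[idx])
}
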