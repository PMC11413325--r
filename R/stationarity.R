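# Unit-root and level-stationarity tests used to gate the ARIMA
# differencing order. Both follow the standard textbook constructions;
# p-values are read from the published asymptotic tables by linear
# interpolation and clipped to the table bounds.

# Dickey-Fuller tau (constant, no trend) asymptotic quantiles
.adf_tab <- list(
  p = c(0.01, 0.025, 0.05, 0.10, 0.90, 0.95, 0.975, 0.99),
  stat = c(-3.43, -3.12, -2.86, -2.57, -0.44, -0.07, 0.23, 0.60))

# KPSS level-stationarity statistic upper-tail critical values
.kpss_tab <- list(
  p = c(0.10, 0.05, 0.025, 0.01),
  stat = c(0.347, 0.463, 0.574, 0.739))

#' Augmented Dickey-Fuller unit-root test
#'
#' Regression of the differenced series on a constant, the lagged level and
#' `k` lagged differences; the t-statistic of the lagged level is compared
#' with the asymptotic Dickey-Fuller distribution (constant, no trend).
#' The null hypothesis is a unit root, so small p-values indicate
#' stationarity. P-values outside the tabulated range are clipped to
#' \[0.01, 0.99\].
#'
#' @param x numeric series.
#' @param lags number of lagged differences; default `trunc((n-1)^(1/3))`.
#' @return list with `statistic`, `p_value`, `lags`.
#' @export
adf_test <- function(x, lags = NULL) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 10) stopf("series too short for the ADF test")
  if (sd(x) == 0) stopf("degenerate input: series is constant")
  k <- lags %||% trunc((n - 1)^(1/3))
  dx <- diff(x)
  e <- embed(dx, k + 1)                      # columns: dx_t, dx_{t-1}, ...
  yt <- e[, 1]
  lvl <- x[(k + 1):(n - 1)]
  fit <- if (k > 0) lm(yt ~ lvl + e[, -1, drop = FALSE]) else lm(yt ~ lvl)
  stat <- summary(fit)$coefficients["lvl", "t value"]
  p <- approx(.adf_tab$stat, .adf_tab$p, xout = stat, rule = 2)$y
  list(statistic = unname(stat), p_value = p, lags = k)
}

#' KPSS level-stationarity test
#'
#' Statistic `sum(S_t^2) / (n^2 * lrv)` with `S_t` the partial sums of the
#' demeaned series and `lrv` the Bartlett-window long-run variance. The null
#' hypothesis is level stationarity, so large statistics (small p-values)
#' indicate non-stationarity. P-values outside the tabulated range are
#' clipped to \[0.01, 0.10\].
#'
#' @param x numeric series.
#' @param lags Bartlett truncation lag; default `trunc(4 * (n/100)^0.25)`.
#' @return list with `statistic`, `p_value`, `lags`.
#' @export
kpss_test <- function(x, lags = NULL) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 10) stopf("series too short for the KPSS test")
  if (sd(x) == 0) stopf("degenerate input: series is constant")
  l <- lags %||% trunc(4 * (n / 100)^0.25)
  e <- x - mean(x)
  s2 <- sum(e^2) / n
  if (l > 0) {
    for (j in seq_len(l)) {
      w <- 1 - j / (l + 1)
      s2 <- s2 + 2 * w * sum(e[(j + 1):n] * e[1:(n - j)]) / n
    }
  }
  stat <- sum(cumsum(e)^2) / (n^2 * s2)
  p <- approx(.kpss_tab$stat, .kpss_tab$p, xout = stat, rule = 2)$y
  list(statistic = unname(stat), p_value = p, lags = l)
}

#' Determine the differencing order from stationarity tests
#'
#' Runs the ADF and KPSS tests on the raw series and returns the smallest
#' differencing order `d` in `{0, 1, 2}` whose d-times-differenced series
#' the KPSS test accepts as level-stationary at level `alpha`; differencing
#' is applied exactly where KPSS indicates non-stationarity. The verdict
#' records both p-values of the undifferenced series, and the series counts
#' as stationary only when both tests agree (ADF rejects its unit-root null
#' and KPSS retains its stationarity null).
#'
#' @param x numeric series.
#' @param alpha significance level for both tests (default 0.05).
#' @param max_d largest differencing order considered (default 2).
#' @return list with `adf_p`, `kpss_p`, `is_stationary`, `d`.
#' @export
determine_d <- function(x, alpha = 0.05, max_d = 2) {
  x <- as.numeric(x)
  if (sd(x) == 0) stopf("degenerate input: series is constant")
  adf_p <- adf_test(x)$p_value
  kpss_p <- kpss_test(x)$p_value
  d <- NA_integer_
  z <- x
  for (cand in 0:max_d) {
    if (kpss_test(z)$p_value > alpha) { d <- cand; break }
    z <- diff(z)
  }
  if (is.na(d)) {
    warnf("series still non-stationary after %d differences; using d=%d",
          max_d, max_d)
    d <- max_d
  }
  list(adf_p = adf_p, kpss_p = kpss_p,
       is_stationary = (adf_p < alpha) && (kpss_p > alpha),
       d = as.integer(d))
}
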