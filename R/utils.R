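# internal helpers shared across modules

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# origin used for synthetic timestamps
.gb_origin <- function() as.POSIXct("2024-01-01 00:00:00", tz = "UTC")

# regular POSIXct grid, half-open [from, to)
time_grid <- function(from, to, by_minutes) {
  seq(from, to - 1, by = by_minutes * 60)
}

is_regular_grid <- function(times, by_minutes = NULL) {
  if (length(times) < 2) return(TRUE)
  d <- diff(as.numeric(times))
  ok <- all(abs(d - d[1]) < 1e-6) && all(d > 0)
  if (ok && !is.null(by_minutes)) ok <- abs(d[1] - by_minutes * 60) < 1e-6
  ok
}

# min-max scaler fitted on training values; degenerate range maps to 0
fit_minmax <- function(x) {
  rng <- range(x, finite = TRUE)
  if (!all(is.finite(rng))) stopf("cannot scale: no finite values")
  span <- rng[2] - rng[1]
  if (span <= 0) span <- 1
  list(min = rng[1], span = span)
}

apply_minmax <- function(x, sc) (x - sc$min) / sc$span

invert_minmax <- function(x, sc) x * sc$span + sc$min

# quiet R CMD check about ggplot2 aesthetic column names
utils::globalVariables(c("reference", "predicted", "risk"))
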