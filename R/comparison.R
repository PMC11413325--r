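# Rank-based statistical harness for comparing forecasters across
# patients: Friedman omnibus test on within-patient ranks, Nemenyi
# post-hoc pairwise comparisons with Holm correction, critical-difference
# values for rank diagrams, and the exact Wilcoxon signed-rank test for
# paired univariate-vs-multivariate comparisons.

#' Friedman rank test on a blocked metric matrix
#'
#' Ranks treatments within each block (patients are blocks; average ranks
#' for ties; ranking follows `better`, so the best treatment gets rank 1),
#' then computes the chi-square approximation
#' `12/(n k (k+1)) * sum(R_j^2) - 3 n (k+1)` with the standard tie
#' correction and a p-value from the chi-square distribution with `k - 1`
#' degrees of freedom.
#'
#' @param matrix numeric matrix, rows = blocks (patients, n >= 2),
#'   columns = treatments (models, k >= 2), no missing cells.
#' @param better `"lower"` if smaller metric values are better (RMSE, MAE,
#'   SE) or `"higher"` (MCC).
#' @return list with `chi2`, `p_value`, `avg_ranks` (named per treatment,
#'   summing to `k (k+1) / 2`), `n`, `k`.
#' @export
friedman_rank_test <- function(matrix, better = c("lower", "higher")) {
  better <- match.arg(better)
  m <- as.matrix(matrix)
  if (any(is.na(m))) stopf("blocked metric matrix has missing cells")
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2) stopf("need at least 2 blocks and 2 treatments")
  vals <- if (better == "lower") m else -m
  ranks <- t(apply(vals, 1, rank))
  R <- colSums(ranks)
  chi2 <- 12 / (n * k * (k + 1)) * sum(R^2) - 3 * n * (k + 1)
  # tie correction: divide by 1 - sum(t^3 - t) / (n k (k^2 - 1))
  ties <- sum(apply(vals, 1, function(row) {
    t <- table(row); sum(t^3 - t)
  }))
  corr <- 1 - ties / (n * k * (k^2 - 1))
  if (corr <= 0) {
    warnf("all ranks tied in every block; Friedman test carries no information")
    chi2 <- 0; p <- 1
  } else {
    chi2 <- chi2 / corr
    p <- pchisq(chi2, df = k - 1, lower.tail = FALSE)
  }
  avg <- R / n
  names(avg) <- colnames(m) %||% paste0("T", seq_len(k))
  list(chi2 = chi2, p_value = p, avg_ranks = avg, n = n, k = k)
}

#' Nemenyi post-hoc pairwise p-values
#'
#' For each treatment pair, the statistic
#' `|Rbar_i - Rbar_j| / sqrt(k (k+1) / (6 n))` is referred to the
#' studentized-range distribution (`q = statistic * sqrt(2)`, `k` groups,
#' infinite degrees of freedom).
#'
#' @param avg_ranks named average ranks (from [friedman_rank_test()]).
#' @param n number of blocks.
#' @param k number of treatments (defaults to `length(avg_ranks)`).
#' @return data frame with columns `a`, `b`, `statistic`, `p_value`,
#'   one row per unordered pair.
#' @export
nemenyi_pairwise <- function(avg_ranks, n, k = length(avg_ranks)) {
  if (k < 2) stopf("need at least two treatments")
  nm <- names(avg_ranks) %||% paste0("T", seq_len(k))
  se <- sqrt(k * (k + 1) / (6 * n))
  pairs <- utils::combn(seq_len(k), 2)
  out <- data.frame(
    a = nm[pairs[1, ]], b = nm[pairs[2, ]],
    statistic = abs(avg_ranks[pairs[1, ]] - avg_ranks[pairs[2, ]]) / se)
  out$p_value <- ptukey(out$statistic * sqrt(2), nmeans = k, df = Inf,
                        lower.tail = FALSE)
  rownames(out) <- NULL
  out
}

#' Holm step-down multiple-testing decisions
#'
#' Sorts the p-values ascending and compares the i-th smallest with
#' `alpha / (m - i + 1)`; rejects until the first failure, retains all
#' hypotheses from there on.
#'
#' @param p_values numeric p-values in \[0, 1\].
#' @param alpha family-wise significance level.
#' @return logical vector in the input order, `TRUE` = rejected.
#' @export
holm_adjust <- function(p_values, alpha = 0.05) {
  if (!length(p_values)) stopf("empty p-value list")
  if (any(p_values < 0 | p_values > 1)) stopf("p-values must lie in [0, 1]")
  m <- length(p_values)
  o <- order(p_values)
  reject <- logical(m)
  for (i in seq_len(m)) {
    if (p_values[o[i]] <= alpha / (m - i + 1)) reject[o[i]] <- TRUE
    else break
  }
  reject
}

#' Critical difference for average-rank diagrams
#'
#' `CD = q_alpha(k) / sqrt(2) * sqrt(k (k+1) / (6 n))` with `q_alpha` the
#' studentized-range critical value at infinite degrees of freedom: the
#' smallest average-rank gap that is significant in the Nemenyi test.
#'
#' @param n number of blocks (patients).
#' @param k number of treatments (models).
#' @param alpha significance level.
#' @return the critical difference in rank units.
#' @export
critical_difference <- function(n, k, alpha = 0.05) {
  if (n < 2 || k < 2) stopf("need n >= 2 and k >= 2")
  q <- qtukey(1 - alpha, nmeans = k, df = Inf)
  if (!is.finite(q)) stopf("unsupported alpha/k combination")
  q / sqrt(2) * sqrt(k * (k + 1) / (6 * n))
}

# exact null distribution of the signed-rank sum W+ for rank vector r
# (doubled to integers to handle average ranks), by convolution
signed_rank_distribution <- function(ranks2) {
  total <- sum(ranks2)
  f <- numeric(total + 1)       # f[w + 1] = number of sign assignments with W2 = w
  f[1] <- 1
  for (r in ranks2) {
    g <- f
    g[(r + 1):(total + 1)] <- g[(r + 1):(total + 1)] + f[1:(total + 1 - r)]
    f <- g
  }
  f
}

#' Exact paired Wilcoxon signed-rank test
#'
#' Computes paired differences, drops exact zeros (recorded in the
#' result), ranks the absolute differences with average ranks for ties,
#' and returns the exact two-sided p-value
#' `p = min(1, 2 min(P(W <= w), P(W >= w)))` from the full null
#' distribution of the positive-rank sum (convolution over all `2^n` sign
#' assignments) when the effective sample size is at most `exact_limit`;
#' beyond that a normal approximation with tie-corrected variance and
#' continuity correction is used.
#'
#' @param a,b paired measurement vectors of equal length.
#' @param exact_limit largest effective n for exact enumeration.
#' @return list with `p_value`, `w_plus`, `w_minus`, `n_effective`,
#'   `n_zero`, `method`.
#' @export
wilcoxon_exact <- function(a, b, exact_limit = 25) {
  if (length(a) != length(b)) stopf("paired vectors must have equal length")
  if (!length(a)) stopf("empty input")
  d <- a - b
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    warnf("all paired differences are zero; p = 1")
    return(list(p_value = 1, w_plus = 0, w_minus = 0, n_effective = 0,
                n_zero = n_zero, method = "degenerate"))
  }
  r <- rank(abs(d))
  w_plus <- sum(r[d > 0]); w_minus <- sum(r[d < 0])
  if (n <= exact_limit) {
    r2 <- as.integer(round(2 * r))          # doubled ranks are integers
    f <- signed_rank_distribution(r2)
    w2 <- round(2 * w_plus)
    cdf_le <- sum(f[seq_len(w2 + 1)]) / 2^n
    cdf_ge <- sum(f[(w2 + 1):length(f)]) / 2^n
    p <- min(1, 2 * min(cdf_le, cdf_ge))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (abs(w_plus - mu) - 0.5) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(z, lower.tail = FALSE))
    method <- "normal"
  }
  list(p_value = p, w_plus = w_plus, w_minus = w_minus, n_effective = n,
       n_zero = n_zero, method = method)
}

#' Full model-comparison report for one blocked metric matrix
#'
#' Runs the study's model-comparison chain on one patients-by-models
#' metric matrix: Friedman omnibus test first; only when its p-value is
#' below `alpha` are the Nemenyi pairwise comparisons, Holm decisions and
#' critical difference computed (the post-hoc layer is gated on the
#' omnibus test).
#'
#' @param matrix blocked metric matrix (rows = patients, columns = models).
#' @param better `"lower"` or `"higher"` (see [friedman_rank_test()]).
#' @param alpha significance level.
#' @return an object of class `comparison_report`: list with
#'   `friedman_chi2`, `friedman_p`, `avg_ranks`, `alpha`, and — when the
#'   omnibus test is significant — `pairwise` (Nemenyi p-values with Holm
#'   decisions) and `cd_value`.
#' @export
compare_models <- function(matrix, better = c("lower", "higher"),
                           alpha = 0.05) {
  better <- match.arg(better)
  fr <- friedman_rank_test(matrix, better)
  rep <- list(friedman_chi2 = fr$chi2, friedman_p = fr$p_value,
              avg_ranks = fr$avg_ranks, alpha = alpha,
              pairwise = NULL, cd_value = NULL)
  if (fr$p_value < alpha) {
    pw <- nemenyi_pairwise(fr$avg_ranks, fr$n, fr$k)
    pw$holm_reject <- holm_adjust(pw$p_value, alpha)
    rep$pairwise <- pw
    rep$cd_value <- critical_difference(fr$n, fr$k, alpha)
  }
  structure(rep, class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison_report> Friedman chi2 = %.3f, p = %.4f\n",
              x$friedman_chi2, x$friedman_p))
  cat("  average ranks:",
      paste(sprintf("%s %.2f", names(x$avg_ranks), x$avg_ranks),
            collapse = ", "), "\n")
  if (is.null(x$pairwise)) {
    cat(sprintf("  omnibus test not significant at alpha = %g; no post-hoc\n",
                x$alpha))
  } else {
    cat(sprintf("  CD = %.3f rank units\n", x$cd_value))
    for (i in seq_len(nrow(x$pairwise)))
      cat(sprintf("  %s vs %s: p = %.4f%s\n", x$pairwise$a[i],
                  x$pairwise$b[i], x$pairwise$p_value[i],
                  if (x$pairwise$holm_reject[i]) " *" else ""))
  }
  invisible(x)
}

#' Critical-difference diagram data
#'
#' Machine-readable description of a CD diagram: treatments ordered by
#' average rank, the critical difference, and the cliques of treatments
#' whose average ranks differ by less than the CD.
#'
#' @param report a [compare_models()] report with a post-hoc layer.
#' @param file optional path to write the structure as JSON.
#' @return list with `treatments`, `avg_ranks`, `cd_value`, `cliques`.
#' @export
cd_diagram_data <- function(report, file = NULL) {
  if (is.null(report$cd_value))
    stopf("report has no post-hoc layer (omnibus test not significant)")
  o <- order(report$avg_ranks)
  rk <- report$avg_ranks[o]
  k <- length(rk)
  cliques <- list()
  for (i in seq_len(k)) {
    j <- max(which(rk - rk[i] < report$cd_value))
    if (j > i) cliques[[length(cliques) + 1]] <- names(rk)[i:j]
  }
  # drop cliques contained in another clique
  keep <- vapply(seq_along(cliques), function(i)
    !any(vapply(seq_along(cliques), function(j)
      i != j && all(cliques[[i]] %in% cliques[[j]]), TRUE)), TRUE)
  out <- list(treatments = names(rk), avg_ranks = unname(rk),
              cd_value = report$cd_value, cliques = cliques[keep])
  if (!is.null(file))
    jsonlite::write_json(out, file, auto_unbox = TRUE, digits = NA)
  out
}
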