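test_that("Friedman closed form holds for perfectly concordant blocks", {
  # all 6 blocks rank the 3 treatments identically: chi2 = 12
  m <- matrix(rep(c(1, 2, 3), each = 6), nrow = 6)
  colnames(m) <- c("a", "b", "c")
  r <- friedman_rank_test(m, "lower")
  expect_equal(r$chi2, 12)
  expect_equal(r$p_value, pchisq(12, 2, lower.tail = FALSE))
  expect_equal(unname(r$avg_ranks), c(1, 2, 3))
  expect_equal(sum(r$avg_ranks), 3 * 4 / 2)
})

test_that("constant blocks carry no information", {
  m <- matrix(5, nrow = 4, ncol = 3)
  expect_warning(r <- friedman_rank_test(m), "tied")
  expect_equal(r$chi2, 0)
  expect_equal(r$p_value, 1)
})

test_that("Friedman agrees with the stats implementation, ties included", {
  set.seed(21)
  for (i in 1:10) {
    m <- matrix(sample(1:4, 18, replace = TRUE), nrow = 6)   # forces ties
    if (any(apply(m, 1, function(r) length(unique(r))) == 1)) next
    ours <- friedman_rank_test(m, "lower")
    ref <- stats::friedman.test(m)
    expect_equal(ours$chi2, unname(ref$statistic))
    expect_equal(ours$p_value, ref$p.value)
  }
})

test_that("Friedman p is calibrated against the within-block permutation null", {
  # exact null: enumerate all 6^4 within-block column orderings (n=4, k=3)
  orders <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                  c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  perm_p <- function(m) {
    obs <- friedman_rank_test(m, "lower")$chi2
    perms <- as.matrix(expand.grid(rep(list(1:6), nrow(m))))
    hits <- 0
    for (i in seq_len(nrow(perms))) {
      mp <- m
      for (b in seq_len(nrow(m))) mp[b, ] <- m[b, orders[perms[i, b], ]]
      if (friedman_rank_test(mp, "lower")$chi2 >= obs - 1e-9) hits <- hits + 1
    }
    hits / nrow(perms)
  }
  # decision-relevant tail: a strongly separated instance
  sep <- matrix(c(1, 2, 3), nrow = 4, ncol = 3, byrow = TRUE) +
    matrix(rnorm(12, 0, 0.01), 4)
  p_perm <- perm_p(sep)
  p_chi2 <- friedman_rank_test(sep, "lower")$p_value
  expect_lt(p_perm, 0.05); expect_lt(p_chi2, 0.05)
  expect_lt(abs(p_perm - p_chi2), 0.05)
  # body of the null: monotone agreement, bounded approximation error
  set.seed(3)
  pp <- pc <- numeric(4)
  for (i in 1:4) {
    m <- matrix(rnorm(12), 4, 3)
    pp[i] <- perm_p(m)
    pc[i] <- friedman_rank_test(m, "lower")$p_value
  }
  expect_equal(order(pp), order(pc))
  expect_lt(max(abs(pp - pc)), 0.25)
})

test_that("Nemenyi p-values follow the studentized range and its symmetries", {
  ranks <- c(a = 2, b = 2, c = 2)
  pw <- nemenyi_pairwise(ranks, n = 6)
  expect_true(all(pw$p_value == 1))
  ranks2 <- c(ctf = 3.00, tml = 7 / 6, dnn = 11 / 6)
  pw2 <- nemenyi_pairwise(ranks2, n = 6)
  gap <- pw2[pw2$a == "ctf" & pw2$b == "tml", ]
  # the CTF-TML rank gap exceeds the critical difference
  expect_gt(gap$statistic * sqrt(3 * 4 / (6 * 6)), critical_difference(6, 3))
  expect_lt(gap$p_value, 0.05)
  # invariance to reversing the ranking direction (4 - rank)
  pw3 <- nemenyi_pairwise(4 - ranks2, n = 6)
  expect_equal(sort(pw3$p_value), sort(pw2$p_value))
})

test_that("Holm decisions follow the step-down trace", {
  expect_equal(holm_adjust(c(0.01, 0.03, 0.04), 0.05),
               c(TRUE, FALSE, FALSE))    # 0.03 > 0.05/2 stops the chain
  expect_equal(holm_adjust(c(1, 1, 1), 0.05), rep(FALSE, 3))
  expect_equal(holm_adjust(0.04, 0.05), TRUE)
  expect_error(holm_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("Holm sits between Bonferroni and unadjusted testing", {
  set.seed(13)
  for (i in 1:30) {
    p <- runif(sample(2:6, 1))^2
    holm <- holm_adjust(p, 0.05)
    bonf <- p <= 0.05 / length(p)
    raw <- p <= 0.05
    expect_true(all(holm[bonf]))      # rejects at least Bonferroni's set
    expect_true(all(raw[holm]))       # never rejects what raw testing keeps
  }
})

test_that("the critical difference matches its closed form and shrinks with n", {
  expect_equal(critical_difference(6, 3, 0.05),
               qtukey(0.95, 3, Inf) / sqrt(2) * sqrt(3 * 4 / (6 * 6)))
  expect_equal(critical_difference(6, 3, 0.05), 1.353, tolerance = 1e-3)
  expect_gt(critical_difference(6, 3), critical_difference(24, 3))
  # two treatments reduce to the simple two-sample form
  expect_equal(critical_difference(9, 2),
               qtukey(0.95, 2, Inf) / sqrt(2) * sqrt(1 / 9) * sqrt(6 / 6))
})

test_that("exact Wilcoxon agrees with full sign enumeration, ties included", {
  set.seed(17)
  for (i in 1:12) {
    n <- sample(4:10, 1)
    a <- round(runif(n, 10, 40), 1)
    b <- a + sample(c(-1, 0, 1), n, replace = TRUE) *
      round(runif(n, 0, 5), 1)
    ours <- wilcoxon_exact(a, b)
    if (ours$n_effective == 0) next
    expect_equal(ours$p_value, wilcoxon_bruteforce(a, b), info = paste(a, b))
  }
})

test_that("Wilcoxon handles zeros, degeneracy and the large-sample path", {
  expect_warning(res <- wilcoxon_exact(c(1, 2, 3), c(1, 2, 3)), "zero")
  expect_equal(res$p_value, 1)
  # five positive differences after one zero drop: p = 2/32
  a <- c(20.56, 18.67, 17.24, 24.08, 21.28, 21.78)
  b <- c(19.35, 18.52, 16.09, 24.08, 18.03, 21.49)
  res <- wilcoxon_exact(a, b)
  expect_equal(res$n_zero, 1)
  expect_equal(res$n_effective, 5)
  expect_equal(res$p_value, 0.0625)
  # beyond the exact limit the normal approximation stays close to exact
  set.seed(30)
  x <- rnorm(30); y <- x + rnorm(30, 0.3)
  exact <- wilcoxon_exact(x, y, exact_limit = 40)
  appr <- wilcoxon_exact(x, y, exact_limit = 25)
  expect_equal(appr$method, "normal")
  expect_equal(appr$p_value, exact$p_value, tolerance = 0.02)
})

test_that("model comparison gates the post-hoc layer on the omnibus test", {
  concordant <- matrix(rep(c(1, 2, 3), each = 6), nrow = 6,
                       dimnames = list(NULL, c("a", "b", "c")))
  rep1 <- compare_models(concordant, "lower")
  expect_false(is.null(rep1$pairwise))
  expect_equal(nrow(rep1$pairwise), 3)
  expect_equal(rep1$cd_value, critical_difference(6, 3))
  set.seed(5)
  noisy <- matrix(rnorm(18), nrow = 6,
                  dimnames = list(NULL, c("a", "b", "c")))
  rep2 <- compare_models(noisy, "lower")
  if (rep2$friedman_p >= 0.05) expect_null(rep2$pairwise)
  cd <- cd_diagram_data(rep1)
  expect_equal(cd$treatments, c("a", "b", "c"))
  expect_error(cd_diagram_data(compare_models(
    matrix(rep(c(1, 2, 3), each = 2), nrow = 2), "lower")), "post-hoc")
})
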