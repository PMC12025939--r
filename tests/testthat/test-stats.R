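test_that("OLS round-trips generating lines and matches the normal equations", {
  x <- seq(0, 100 / 3, length.out = 34)
  fit <- ols_fit(x, 39.5 - 0.268 * x)
  expect_equal(fit$slope, -0.268, tolerance = 1e-9)
  expect_equal(fit$intercept, 39.5, tolerance = 1e-9)
  expect_equal(fit$rss, 0, tolerance = 1e-16)

  cfit <- ols_fit(1:10, rep(35, 10))
  expect_equal(cfit$slope, 0)
  expect_equal(cfit$intercept, 35)

  set.seed(3)
  xh <- c(1.2, 4.5, 7.0, 9.9, 15.3)
  yh <- c(30.1, 28.7, 31.5, 26.0, 25.2)
  f1 <- ols_fit(xh, yh)
  f2 <- normal_equations_fit(xh, yh)
  expect_equal(f1$slope, f2$slope, tolerance = 1e-10)
  expect_equal(f1$intercept, f2$intercept, tolerance = 1e-10)
  expect_equal(f1$rss, f2$rss, tolerance = 1e-10)

  expect_error(ols_fit(c(1, 2), c(3, 4)), "at least 3")
  expect_error(ols_fit(rep(2, 5), 1:5), "all equal")
})

test_that("Chow test detects no change on identical data and flags perfect fits", {
  set.seed(11)
  x <- seq(0, 33, length.out = 20)
  y <- 35 - 0.2 * x + rnorm(20, 0, 2)
  same <- chow_test(list(x = x, y = y), list(x = x, y = y))
  expect_equal(same$f_stat, 0, tolerance = 1e-8)
  expect_equal(same$p_value, 1, tolerance = 1e-8)
  expect_equal(same$df1, 2L)
  expect_equal(same$df2, 40L - 4L)

  # two perfect parallel lines offset by 10 ms: degenerate, p = 0
  sep <- chow_test(list(x = x, y = 30 - 0.2 * x),
                   list(x = x, y = 40 - 0.2 * x))
  expect_true(sep$degenerate)
  expect_equal(sep$p_value, 0)

  ident <- chow_test(list(x = x, y = 30 - 0.2 * x),
                     list(x = x, y = 30 - 0.2 * x))
  expect_true(ident$degenerate)
  expect_equal(ident$p_value, 1)
})

test_that("Chow F matches an explicit residual-sum-of-squares assembly", {
  set.seed(21)
  for (rep in 1:5) {
    xa <- runif(6, 0, 33); ya <- 35 - 0.2 * xa + rnorm(6, 0, 2)
    xb <- runif(6, 0, 33); yb <- 30 + 0.1 * xb + rnorm(6, 0, 2)
    got <- chow_test(list(x = xa, y = ya), list(x = xb, y = yb))
    want <- explicit_chow_f(xa, ya, xb, yb)
    expect_equal(got$f_stat, want$f, tolerance = 1e-8)
    expect_equal(got$p_value, want$p, tolerance = 1e-8)
  }
})

test_that("Chow power is monotone in the true slope difference", {
  set.seed(31)
  x <- seq(0, 33.3, length.out = 34)
  rate <- vapply(c(0, 0.1, 0.2, 0.4), function(dslope) {
    rej <- vapply(1:300, function(i) {
      a <- list(x = x, y = 35 - 0.2 * x + rnorm(34, 0, 3))
      b <- list(x = x, y = 35 - (0.2 + dslope) * x + rnorm(34, 0, 3))
      chow_test(a, b)$p_value < 0.05
    }, logical(1))
    mean(rej)
  }, numeric(1))
  expect_true(all(diff(rate) >= 0))
  expect_gt(rate[4], 0.9)
})

test_that("exact Wilcoxon matches literal enumeration for all n <= 10", {
  w <- wilcoxon_signed_rank(c(1, 2, 3, 4, 5))
  expect_equal(w$statistic, 0)
  expect_equal(w$p_value, 2 / 32)

  sym <- wilcoxon_signed_rank(c(3, -3))
  expect_equal(sym$p_value, 1)

  set.seed(41)
  for (n in 2:10) {
    for (rep in 1:5) {
      d <- round(rnorm(n, 0.3, 1), 1)       # rounding induces ties and zeros
      if (all(d == 0)) d[1] <- 0.5
      got <- wilcoxon_signed_rank(d)
      expect_equal(got$p_value, enum_signed_rank_p(d), tolerance = 1e-12,
                   info = sprintf("n = %d rep = %d", n, rep))
    }
  }

  # tie-free case agrees with the reference exact distribution
  d <- c(1.3, -0.4, 2.2, 0.7, -1.8, 3.1, 0.2, -2.6, 1.1)
  ref <- stats::wilcox.test(d, exact = TRUE)
  expect_equal(wilcoxon_signed_rank(d)$p_value, ref$p.value, tolerance = 1e-12)

  allz <- wilcoxon_signed_rank(c(0, 0, 0))
  expect_true(allz$all_zero)
  expect_equal(allz$p_value, 1)
})

test_that("normal approximation is close to exact near the n = 25 switchover", {
  set.seed(51)
  d <- rnorm(24, 0.4, 1)
  ex <- wilcoxon_signed_rank(d, mode = "exact")$p_value
  no <- wilcoxon_signed_rank(d, mode = "normal")$p_value
  expect_lt(abs(ex - no), 0.02)
  big <- wilcoxon_signed_rank(rnorm(40, 0.2, 1))
  expect_equal(big$method, "normal-approximation")
})

test_that("paired t-test reproduces hand arithmetic and its degenerate guards", {
  flat <- paired_t_test(c(2, 0), c(1, 1))   # d = {1, -1}
  expect_equal(flat$t, 0)
  expect_equal(flat$p_value, 1)

  expect_error(paired_t_test(c(3, 4, 5, 6), c(1, 2, 3, 4)), "zero variance")

  # d = {1, 2, 3, 4, 5}: mean 3, sd sqrt(2.5), t = 3 / sqrt(0.5)
  ht <- paired_t_test(c(2, 4, 6, 8, 10), c(1, 2, 3, 4, 5))
  expect_equal(ht$t, 3 / sqrt(2.5 / 5), tolerance = 1e-12)
  expect_equal(ht$df, 4)
  expect_equal(ht$p_value, 2 * pt(-ht$t, 4), tolerance = 1e-12)

  # consistency with the one-sample t on the differences
  set.seed(61)
  a <- rnorm(12, 40, 5); b <- a - rnorm(12, 1, 2)
  one <- t.test(a - b)
  expect_equal(paired_t_test(a, b)$t, unname(one$statistic), tolerance = 1e-12)
})

test_that("Shapiro-Wilk flag separates normal from log-normal samples", {
  set.seed(71)
  expect_true(shapiro_wilk_check(rnorm(500))$normal)
  expect_false(shapiro_wilk_check(exp(rnorm(500)))$normal)
  expect_silent(shapiro_wilk_check(c(-1, 0, 1)))
  expect_error(shapiro_wilk_check(rep(4, 10)), "constant")
})

test_that("loess smoothing reproduces lines exactly and shrinks noise variance", {
  mk_profile <- function(y) {
    structure(list(bin_centers = seq(0.5, 99.5, by = 1), bin_means = y,
                   bin_counts = rep(3L, 100), n_bins = 100L),
              class = "t2_profile")
  }
  lin <- mk_profile(30 + 0.1 * seq(0.5, 99.5, by = 1))
  sm <- loess_smooth(lin, span = 0.4)
  expect_lt(max(abs(sm$smoothed_t2_ms - lin$bin_means)), 1e-6)
  sm1 <- loess_smooth(lin, span = 1)
  expect_lt(max(abs(sm1$smoothed_t2_ms - lin$bin_means)), 1e-6)

  set.seed(81)
  noisy <- mk_profile(40 + rnorm(100, 0, 3))
  smn <- loess_smooth(noisy, span = 0.4)
  expect_lt(var(smn$smoothed_t2_ms), var(noisy$bin_means))

  expect_error(loess_smooth(lin, span = 0.01), "at least 3 points")
})

test_that("segment slopes of noisy profiles fall inside their analytic 95% CIs", {
  set.seed(91)
  x <- seq(0.5, 33, by = 1)       # one segment's bin centers
  slope <- -0.268; icept <- 39.5; sigma <- 2
  covered <- vapply(1:500, function(i) {
    y <- icept + slope * x + rnorm(length(x), 0, sigma)
    f <- ols_fit(x, y)
    se <- sqrt(f$rss / (f$n - 2) / sum((x - mean(x))^2))
    tcrit <- qt(0.975, f$n - 2)
    abs(f$slope - slope) <= tcrit * se
  }, logical(1))
  expect_gte(mean(covered), 0.93)
})
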