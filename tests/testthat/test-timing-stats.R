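test_that("MAD filter reproduces the hand-worked example", {
  x <- c(-0.10, 0, 0.05, 0.10, 10)
  # median 0.05, MAD 0.05, cutoff 3 * 1.4826 * 0.05 ~ 0.222
  out <- remove_outliers_mad(x)
  expect_equal(out$removed, 10)
  expect_equal(sort(out$kept), c(-0.10, 0, 0.05, 0.10))
  same <- remove_outliers_mad(rep(2, 5))
  expect_equal(length(same$removed), 0)
})

test_that("MAD filter agrees with an independent brute force", {
  set.seed(13)
  for (i in 1:60) {
    n <- sample(5:50, 1)
    x <- rnorm(n) + sample(c(0, 5), n, replace = TRUE, prob = c(0.9, 0.1))
    expect_identical(remove_outliers_mad(x)$is_outlier,
                     brute_mad_outliers(x))
    expect_identical(remove_outliers_mad(x, scale = "raw")$is_outlier,
                     brute_mad_outliers(x, c_scale = 1))
  }
})

test_that("MAD filter is order-invariant and handles a zero MAD", {
  set.seed(14)
  x <- c(rnorm(30), 8, -9)
  p <- sample(x)
  expect_setequal(remove_outliers_mad(x)$kept, remove_outliers_mad(p)$kept)
  expect_message(z <- remove_outliers_mad(c(1, 1, 1, 1, 9)), "MAD is zero")
  expect_equal(z$removed, 9)
})

test_that("lags from the default generator pass the outlier filter almost intact", {
  l <- draw_lags(lag_model(), 5000, seed = 3)
  out <- remove_outliers_mad(l)
  expect_lt(100 * sum(out$is_outlier) / length(l), 5)
})

test_that("Lilliefors test rejects the skewed lag distribution and not the null", {
  rej <- vapply(1:20, function(s) {
    ks_normality(draw_lags(lag_model(), 1000, seed = s)) < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.9)

  set.seed(15)
  pvals <- vapply(1:120, function(i) ks_normality(rnorm(200)), numeric(1))
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)

  expect_error(ks_normality(rnorm(4)), "n >= 5")
  expect_warning(p0 <- ks_normality(rep(1, 10)), "zero variance")
  expect_equal(p0, 0)
})

test_that("skewness statistic matches the moment formula and flags asymmetry", {
  expect_equal(skewness_test(rep(c(-1, 0, 1), 5))$g1, 0)

  x <- c(1, 2, 3, 10)
  # direct evaluation of the adjusted Fisher-Pearson formula
  n <- 4; m <- mean(x)
  g1 <- (mean((x - m)^3) / mean((x - m)^2)^1.5) * sqrt(n * (n - 1)) / (n - 2)
  x8 <- c(x, x)  # n >= 8 for the test itself
  expect_gt(skewness_test(x8)$g1, 0)
  expect_equal(breathturn:::sample_skewness(x), g1)

  expect_error(skewness_test(rep(1, 10)), "zero-variance")
  expect_error(skewness_test(rnorm(7)), "n >= 8")

  # invariant under positive affine rescaling
  set.seed(16)
  y <- rgamma(100, 3)
  expect_equal(skewness_test(y)$g1, skewness_test(5 * y + 2)$g1,
               tolerance = 1e-9)

  # lags from the default generator are left-skewed
  l <- draw_lags(lag_model(), 2000, seed = 4)
  expect_lt(skewness_test(l)$g1, 0)
})

test_that("skewness agrees with an independent implementation", {
  testthat::skip_if_not_installed("e1071")
  set.seed(17)
  x <- rgamma(500, 2)
  expect_equal(breathturn:::sample_skewness(x, adjust = FALSE),
               e1071::skewness(x, type = 1), tolerance = 1e-12)
  expect_equal(breathturn:::sample_skewness(x, adjust = TRUE),
               e1071::skewness(x, type = 2), tolerance = 1e-12)
})

test_that("density mode finds point masses, mixtures, and generator modes", {
  expect_equal(density_mode(rep(-0.2, 60)), -0.2)

  hits <- vapply(1:20, function(s) {
    set.seed(200 + s)
    x <- c(rnorm(1600, -0.2, 0.05), rnorm(400, 0.1, 0.05))
    abs(density_mode(x) + 0.2) <= 0.025
  }, logical(1))
  expect_true(all(hits))

  l <- draw_lags(lag_model(), 5000, seed = 5)
  expect_lt(abs(density_mode(remove_outliers_mad(l)$kept,
                             bandwidth = 0.05) + 0.2), 0.025)

  set.seed(18)
  x <- rnorm(500)
  expect_equal(density_mode(x + 3), density_mode(x) + 3, tolerance = 2e-3)
  expect_error(density_mode(rnorm(10)), "n >= 50")
})

test_that("condition comparison matches t.test and a permutation oracle", {
  set.seed(19)
  a <- rnorm(400, -0.206, 0.175)
  b <- rnorm(400, -0.180, 0.162)
  cmp <- compare_conditions(a, b)
  ref <- t.test(a, b, var.equal = TRUE)
  expect_equal(cmp$student$t, unname(ref$statistic))
  expect_equal(cmp$student$p, ref$p.value)
  expect_equal(cmp$means, c(a = mean(a), b = mean(b)))

  # permutation oracle agrees on the rejection decision at alpha = 0.05
  pool <- c(a, b)
  obs <- abs(mean(a) - mean(b))
  perm <- vapply(1:2000, function(i) {
    idx <- sample.int(800, 400)
    abs(mean(pool[idx]) - mean(pool[-idx]))
  }, numeric(1))
  p_perm <- mean(perm >= obs)
  expect_equal(p_perm < 0.05, cmp$welch$p < 0.05)

  same <- compare_conditions(a, a)
  expect_equal(same$student$t, 0)
  expect_equal(same$student$p, 1)
  const <- compare_conditions(rep(1, 5), rep(1, 7))
  expect_equal(const$student$p, 1)
})

test_that("the lag summary is internally consistent", {
  set.seed(20)
  rec <- data.frame(delta_t = draw_lags(lag_model(), 400, seed = 6),
                    peak_time = runif(400, 0, 500),
                    condition = rep(c("human", "robot"), 200))
  s <- summarize_deltas(rec, n_peaks = 2000)
  expect_equal(s$n_total, s$n_kept + s$n_removed)
  expect_equal(s$pct_removed, 100 * s$n_removed / s$n_total)
  expect_equal(s$cdf$cum[nrow(s$cdf)], 1)
  expect_true(all(diff(s$cdf$cum) > 0))
  expect_false(is.unsorted(s$cdf$delta_t))
  expect_equal(s$pct_resp_plus, 100 * s$n_resp_plus / 2000)
  expect_false(is.null(s$group))
  expect_lt(s$skewness, 0)
  expect_output(print(s), "Resp\\+")
})
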