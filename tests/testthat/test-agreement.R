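test_that("Spearman correlation handles monotone series and ties", {
  a <- c(1, 2, 3, 4, 5)
  expect_equal(spearman_correlation(a, a * 2 + 1)$rho, 1)
  expect_equal(spearman_correlation(a, -a^3)$rho, -1)
  r <- spearman_correlation(c(1, 2, 2, 3), c(1, 3, 2, 4))
  expect_equal(round(r$rho, 4), 0.9487)
  expect_equal(r$method, "exact permutation")
  expect_true(r$p > 0 && r$p <= 1)
  # exact permutation p agrees with full enumeration done by hand for n = 3:
  # the 6 permutations of a perfectly correlated pair give |rho| = 1 twice
  expect_equal(spearman_correlation(c(1, 2, 3), c(2, 4, 9))$p, 2 / 6)
  expect_error(spearman_correlation(c(1, 1, 1), c(1, 2, 3)), "constant")
})

test_that("large-n Spearman p matches the t approximation", {
  set.seed(5)
  a <- rnorm(30); b <- a + rnorm(30)
  r <- spearman_correlation(a, b)
  tt <- r$rho * sqrt(28 / (1 - r$rho^2))
  expect_equal(r$p, 2 * pt(-abs(tt), 28))
  expect_equal(r$rho, suppressWarnings(
    cor.test(a, b, method = "spearman")$estimate[[1]]))
})

test_that("Bland-Altman reproduces hand-computed examples", {
  # constant offset: b = a + 2
  a <- c(1, 5, 9, 13)
  ba <- bland_altman(a, a + 2)
  expect_equal(ba$bias, -2)
  expect_equal(ba$sd_diff, 0)
  expect_equal(ba$loa, c(-2, -2))
  expect_equal(ba$loa_width, 0)
  expect_equal(ba$pct_within, 100)

  # d = (-1, 0, 1): bias 0, sd 1, LoA +/- 1.96, t-based CI +/- 4.3027/sqrt(3)
  ba3 <- bland_altman(c(9, 10, 11), c(10, 10, 10))
  expect_equal(ba3$bias, 0)
  expect_equal(ba3$sd_diff, 1)
  expect_equal(ba3$loa, c(-1.96, 1.96))
  expect_equal(ba3$bias_ci, c(-1, 1) * qt(0.975, 2) / sqrt(3))
  expect_equal(round(ba3$bias_ci[2], 3), 2.484)
  expect_false(ba3$bias_significant)
  expect_equal(ba3$loa_width, 2 * 1.96 * ba3$sd_diff)
})

test_that("about 95% of Normal differences fall inside the limits", {
  set.seed(100)
  d <- rnorm(10000)
  ba <- bland_altman(d + 5, rep(5, 10000))
  expect_gt(ba$pct_within, 94.5)
  expect_lt(ba$pct_within, 95.5)
})

test_that("proportional-bias regression matches closed-form OLS", {
  r <- proportional_bias_regression(c(1, 2, 3), c(1, 3, 2))
  expect_equal(r$slope, 0.5)
  expect_equal(r$intercept, 1.0)

  means <- c(1, 2, 3, 4)
  exact <- proportional_bias_regression(means, 0.1 * means)
  expect_equal(exact$slope, 0.1)
  expect_equal(exact$intercept, 0, tolerance = 1e-12)
  expect_true(exact$exact_fit)
  expect_equal(exact$p, 0)

  flat <- proportional_bias_regression(means, rep(2, 4))
  expect_equal(flat$slope, 0)
  expect_equal(flat$F, 0)
  expect_equal(flat$p, 1)
  expect_error(proportional_bias_regression(rep(1, 4), 1:4), "constant")
})

test_that("the log branch equals the raw branch on log-transformed inputs", {
  set.seed(9)
  a <- rlnorm(40, 3, 0.4); b <- a * rlnorm(40, 0.02, 0.05)
  ba_log <- bland_altman(a, b, log_transform = TRUE)
  ba_manual <- bland_altman(log(a), log(b))
  for (f in c("bias", "sd_diff", "loa", "bias_ci", "reg_slope", "reg_F")) {
    expect_equal(ba_log[[f]], ba_manual[[f]])
  }
  expect_error(bland_altman(c(-1, 2, 3), c(1, 2, 3), log_transform = TRUE),
               "positive")
})

test_that("Shieh bounds decide agreement against the margins", {
  set.seed(50)
  d <- rnorm(50, 0, 0.1)
  wide <- shieh_agreement_test(d, delta = c(-1, 1))
  expect_true(wide$reject_h0)
  narrow <- shieh_agreement_test(d, delta = c(-0.05, 0.05))
  expect_false(narrow$reject_h0)
  expect_lt(wide$bound_low, wide$bound_high)
  expect_equal(wide$gamma, qnorm(0.975))
  expect_equal(wide$conf, 0.9)
  # containment rule
  expect_equal(wide$reject_h0,
               -1 < wide$bound_low && wide$bound_high < 1)
  expect_error(shieh_agreement_test(d, delta = c(1, -1)), "low < high")
  expect_error(shieh_agreement_test(d, delta = c(-1, 1), alpha = 0.7),
               "alpha")
})

test_that("Shieh bounds approach +/- gamma in large samples", {
  set.seed(123)
  d <- rnorm(100000)
  sh <- shieh_agreement_test(d, delta = c(-3, 3))
  expect_lt(abs(sh$bound_low + 1.96), 0.02)
  expect_lt(abs(sh$bound_high - 1.96), 0.02)
})

test_that("degenerate zero-spread differences give point bounds", {
  sh <- shieh_agreement_test(rep(0.3, 10), delta = c(-1, 1))
  expect_equal(sh$bound_low, 0.3)
  expect_equal(sh$bound_high, 0.3)
  expect_true(sh$reject_h0)
})

test_that("compare_methods composes the full validation workflow", {
  a <- c(10, 20, 30, 40, 50)
  self <- compare_methods(a, a, delta = c(-1, 1))
  expect_equal(self$spearman$rho, 1)
  expect_equal(self$bland_altman_raw$bias, 0)
  expect_equal(self$bland_altman_raw$loa, c(0, 0))
  expect_true(self$shieh_raw$reject_h0)

  # parameter recovery mirroring a realistic bias/LoA geometry
  set.seed(206)
  n <- 206
  b <- rlnorm(n, log(34), 0.5)
  aa <- b + rnorm(n, 0.747, 2.208)
  cmp <- compare_methods(aa, b, unit = "kPa")
  expect_lt(abs(cmp$bland_altman_raw$bias - 0.747), 2 * 2.208 / sqrt(n))
  expect_true(cmp$spearman$rho > 0.9)
  expect_false(is.null(cmp$bland_altman_log))

  expect_error(compare_methods(1:5, 1:4), "equal length")
})

test_that("data-frame inputs are matched on the clip identifier", {
  a <- data.frame(clip = c("c1", "c2", "c3", "c4"), mean = c(10, 20, 30, 40))
  b <- data.frame(clip = c("c4", "c2", "c1", "c3", "c9"),
                  mean = c(41, 19, 12, 29, 99))
  expect_warning(cmp <- compare_methods(a, b), "unmatched")
  expect_equal(cmp$n, 4L)
  expect_equal(cmp$bland_altman_raw$bias,
               mean(c(10 - 12, 20 - 19, 30 - 29, 40 - 41)))
})
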