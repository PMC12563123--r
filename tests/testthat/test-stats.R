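test_that("Shapiro-Wilk W is exact for n = 3 and affine invariant", {
  res <- shapiro_wilk(c(1, 2, 3))
  # numerator (0.7071 * 2)^2 = 2 equals the denominator for this sample
  expect_equal(res$W, 1.0, tolerance = 1e-10)
  expect_equal(res$p_value, 1.0, tolerance = 1e-6)
  set.seed(4)
  x <- rnorm(25)
  expect_equal(shapiro_wilk(3.7 * x - 11)$W, shapiro_wilk(x)$W,
               tolerance = 1e-12)
})

test_that("Shapiro-Wilk matches the reference implementation", {
  set.seed(101)
  for (i in 1:50) {
    n <- sample(4:200, 1)
    x <- switch(1 + i %% 3,
                rnorm(n), rexp(n), runif(n)^2)
    got <- shapiro_wilk(x)
    ref <- shapiro.test(x)
    expect_equal(got$W, unname(ref$statistic), tolerance = 1e-6)
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-4)
  }
})

test_that("Shapiro-Wilk rejects out-of-range and degenerate samples", {
  expect_error(shapiro_wilk(c(1, 2)), "3 <= n")
  expect_error(shapiro_wilk(rep(1, 10)), "zero variance")
})

test_that("Shapiro-Wilk holds its nominal type-I error", {
  set.seed(77)
  reps <- 4000
  rej <- 0
  for (i in seq_len(reps)) {
    if (shapiro_wilk(rnorm(20))$p_value < 0.05) rej <- rej + 1
  }
  rate <- rej / reps
  ci <- 2.58 * sqrt(0.05 * 0.95 / reps)
  expect_lt(abs(rate - 0.05), ci)
})

test_that("Filliben probabilities follow the three-branch formula", {
  p3 <- filliben_quantiles(3)
  expect_equal(p3, c(1 - 0.5^(1 / 3), (2 - 0.3175) / 3.365, 0.5^(1 / 3)))
  expect_equal(p3, c(0.2063, 0.5, 0.7937), tolerance = 1e-4)
  p2 <- filliben_quantiles(2)
  expect_equal(p2, c(1 - sqrt(0.5), sqrt(0.5)))
  expect_error(filliben_quantiles(1), "n >= 2")
})

test_that("Filliben probabilities are increasing and symmetric up to 1e4", {
  for (n in c(2, 3, 5, 17, 100, 1234, 10000)) {
    p <- filliben_quantiles(n)
    expect_true(all(diff(p) > 0))
    expect_equal(p + rev(p), rep(1, n), tolerance = 1e-12)
  }
})

test_that("probability-plot R2 flags linearity and bimodality", {
  # sample equal to its own theoretical quantiles is perfectly linear
  q <- qnorm(filliben_quantiles(20))
  expect_equal(probability_plot_r2(q), 1.0, tolerance = 1e-12)
  expect_equal(probability_plot_r2(5 * q + 2), 1.0, tolerance = 1e-12)
  # strongly bimodal fixture: two separated normals
  set.seed(12)
  bim <- c(rnorm(25, -8, 0.3), rnorm(25, 8, 0.3))
  expect_lt(probability_plot_r2(bim), 0.9)
})

test_that("normality verdict encodes the p > 0.05 AND R2 > 0.9 rule", {
  set.seed(5)
  good <- rnorm(40)
  res <- normality_screen(good)
  expect_identical(res$verdict,
                   if (res$p_value > 0.05 && res$r_squared > 0.9)
                     "normal-supported" else "rejected")
  bad <- c(rnorm(25, -8, 0.3), rnorm(25, 8, 0.3))
  expect_identical(normality_screen(bad)$verdict, "rejected")
})

test_that("Welch t reproduces the hand-computed example", {
  res <- welch_t(c(1, 2, 3), c(2, 3, 4))
  expect_equal(res$t, -sqrt(1.5), tolerance = 1e-10)  # -1.224745
  expect_equal(res$df, 4.0, tolerance = 1e-10)
  expect_false(res$significant)
  same <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)
})

test_that("Welch t matches the reference implementation", {
  set.seed(202)
  for (i in 1:50) {
    x <- rnorm(sample(5:40, 1), sd = runif(1, 0.5, 3))
    y <- rnorm(sample(5:40, 1), mean = runif(1, -1, 1))
    got <- welch_t(x, y)
    ref <- t.test(x, y, var.equal = FALSE)
    expect_equal(got$t, unname(ref$statistic), tolerance = 1e-6)
    expect_equal(got$df, unname(ref$parameter), tolerance = 1e-6)
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-4)
  }
})

test_that("Welch df stays inside its theoretical bracket", {
  set.seed(303)
  for (i in 1:50) {
    n1 <- sample(3:20, 1); n2 <- sample(3:20, 1)
    res <- welch_t(rnorm(n1, sd = runif(1, 0.2, 4)), rnorm(n2))
    expect_gte(res$df, min(n1, n2) - 1 - 1e-9)
    expect_lte(res$df, n1 + n2 - 2 + 1e-9)
  }
})

test_that("degenerate Welch inputs are refused", {
  expect_error(welch_t(1, c(1, 2)), "n >= 2")
  expect_error(welch_t(rep(2, 5), rep(3, 6)), "variances are zero")
  # one-sided degeneracy is fine
  expect_true(is.finite(welch_t(rep(2, 5), c(1, 2, 3))$t))
})

test_that("box-plot summaries follow the type-7 quartile convention", {
  s <- summarize_distribution(1:100)
  expect_equal(s$median, 50.5)
  expect_equal(s$q1, 25.75)
  expect_equal(s$q3, 75.25)
  expect_equal(s$iqr, 49.5)
  expect_equal(s$whisker_low, 1)
  expect_equal(s$whisker_high, 100)
  expect_length(s$outliers, 0)
  # constant sample: zero IQR, no outliers
  s0 <- summarize_distribution(rep(2, 8))
  expect_equal(s0$iqr, 0)
  expect_length(s0$outliers, 0)
  # a single injected extreme is exactly the flagged point
  s1 <- summarize_distribution(c(rnorm(30), 50))
  expect_equal(s1$outliers, 50)
})
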