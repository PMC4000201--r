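test_that("the stationarity test behaves like a calibrated chi-squared test", {
  set.seed(91)
  r <- psr_test(rnorm(2046))
  expect_true(r$p_time >= 0 && r$p_time <= 1)
  expect_equal(unname(r$df["time"]), 5)
  # a variance step is strongly rejected
  step <- c(rnorm(1023), 3 * rnorm(1023))
  expect_lt(psr_test(step)$p_time, 1e-4)
  # reversal invariance: reversing a series whose length is a multiple of
  # the segment count reverses segments and leaves each periodogram (and
  # hence the statistic) unchanged
  x <- as.numeric(arima.sim(list(ar = 0.5), 2046))
  expect_equal(psr_test(x)$statistics, psr_test(rev(x))$statistics)
  expect_error(psr_test(rep(1, 512)), "zero-variance")
  expect_error(psr_test(rnorm(20), 6, 6), "too short")
})

test_that("Jensen-Shannon divergence has its closed-form properties", {
  expect_equal(js_divergence(c(0.3, 0.7), c(0.3, 0.7)), 0)
  expect_equal(js_divergence(c(1, 0), c(0, 1)), log(2))
  expect_equal(js_divergence(c(1, 0), c(0, 1), base = "bits"), 1)
  set.seed(2)
  for (i in 1:5) {
    p <- runif(6); p <- p / sum(p)
    q <- runif(6); q <- q / sum(q)
    # independent oracle: KL-based decomposition
    m <- (p + q) / 2
    kl <- function(a, b) sum(ifelse(a > 0, a * log(a / b), 0))
    expect_equal(js_divergence(p, q), (kl(p, m) + kl(q, m)) / 2,
                 tolerance = 1e-12)
    expect_equal(js_divergence(p, q), js_divergence(q, p))  # symmetry
    expect_gte(js_divergence(p, q), 0)
    expect_lte(js_divergence(p, q), log(2))
  }
  # square root of JSD behaves like a metric on spot-checked triples
  set.seed(3)
  for (i in 1:5) {
    ps <- replicate(3, { v <- runif(4); v / sum(v) }, simplify = FALSE)
    d <- function(a, b) sqrt(js_divergence(a, b))
    expect_lte(d(ps[[1]], ps[[3]]),
               d(ps[[1]], ps[[2]]) + d(ps[[2]], ps[[3]]) + 1e-12)
  }
  expect_error(js_divergence(c(0.5, 0.6), c(0.5, 0.5)), "probability")
})

test_that("Wilks' lambda reduces to the t-statistic in the univariate limit", {
  set.seed(5)
  a <- rnorm(25); b <- rnorm(30) + 0.8
  wl <- wilks_lambda(list(a, b))
  n <- length(a) + length(b)
  sp <- sqrt(((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) / (n - 2))
  tstat <- (mean(a) - mean(b)) / (sp * sqrt(1 / length(a) + 1 / length(b)))
  expect_equal(wl$lambda, 1 / (1 + tstat^2 / (n - 2)), tolerance = 1e-12)
  expect_true(wl$lambda > 0 && wl$lambda <= 1)
  # identical means: lambda near 1, non-significant
  g1 <- matrix(rnorm(400), 200, 2); g2 <- matrix(rnorm(400), 200, 2)
  wl2 <- wilks_lambda(list(g1, g2))
  expect_gt(wl2$lambda, 0.97)
  expect_gt(wl2$p_value, 0.05)
  expect_error(wilks_lambda(list(matrix(rnorm(4), 2), matrix(rnorm(4), 2))),
               "more observations")
})

test_that("normality gating chooses between t and Mann-Whitney", {
  set.seed(7)
  a <- rnorm(30); b <- rnorm(30) + 3
  res <- trial_comparison(a, b)
  expect_equal(res$test, "t")
  expect_lt(res$p_value, 0.001)
  # heavy tails push the gate to the rank test
  ca <- rcauchy(60); cb <- rcauchy(60)
  res2 <- trial_comparison(ca, cb)
  expect_equal(res2$test, "mann-whitney")
  # near-identical samples: large p
  x <- rnorm(40)
  res3 <- trial_comparison(x, x + rnorm(40, 0, 1e-3))
  expect_gt(res3$p_value, 0.5)
  expect_error(trial_comparison(rnorm(3), rnorm(10)), "at least 4")
  expect_error(trial_comparison(rep(1, 10), rnorm(10)), "degenerate")
})

test_that("lilliefors wrapper validates input and detects non-normality", {
  set.seed(10)
  expect_lt(lilliefors_test(rexp(100))$p_value, 0.01)
  p <- lilliefors_test(rnorm(100))$p_value
  expect_true(p >= 0 && p <= 1)
  expect_error(lilliefors_test(rep(2, 10)), "constant")
  expect_error(lilliefors_test(rnorm(3)), "n >= 4")
})

test_that("certainty margins are bounded and monotone under sharpening", {
  expect_equal(certainty_measure(c(1, 0, 0))$certainty, 1)
  expect_equal(certainty_measure(rep(1 / 4, 4))$certainty, 0)
  set.seed(6)
  for (i in 1:10) {
    p <- runif(5); p <- p / sum(p)
    onehot <- as.numeric(seq_along(p) == which.max(p))
    mixed <- 0.5 * p + 0.5 * onehot
    expect_gte(certainty_measure(rbind(mixed))$certainty,
               certainty_measure(rbind(p))$certainty)
  }
  post <- rbind(c(0.9, 0.1), c(0.6, 0.4), c(0.2, 0.8), c(0.5, 0.5))
  cm <- certainty_measure(post, trials = c(1, 1, 2, 2))
  expect_equal(cm$by_trial$certainty, c(mean(c(0.8, 0.2)), mean(c(0.6, 0))))
})
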