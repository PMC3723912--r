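test_that("detrend removes constants and lines exactly", {
  t <- 0:30
  expect_equal(detrend(t, rep(5, 31), "linear"), rep(0, 31))
  expect_equal(detrend(t, 3 + 0.7 * t, "linear"), rep(0, 31),
               tolerance = 1e-10)
  y <- rnorm(31)
  expect_identical(detrend(t, y, "none"), y)
})

test_that("detrending a cosine-plus-line recovers the oscillation", {
  # many full cycles keep the spectral leakage of the OLS line negligible
  t <- seq(0, 480, 0.5)
  osc <- 300 * cos(2 * pi * (t - 4) / 24)
  y <- 50 + 2 * t + osc
  expect_gt(cor(detrend(t, y, "linear"), osc), 0.999)
})

test_that("fit_harmonics is exact on a matched cosine and worse off-period", {
  t <- 0:96
  y <- 400 * cos(2 * pi * t / 24)
  f24 <- fit_harmonics(t, y, 24, 1)
  expect_lt(f24$rss, 1e-12)
  expect_equal(unname(f24$coefficients["cos1"]), 400, tolerance = 1e-8)
  f30 <- fit_harmonics(t, y, 30, 1)
  expect_gt(f30$rss, f24$rss)
})

test_that("OLS harmonic rss never exceeds total sum of squares", {
  set.seed(4)
  t <- 0:47
  y <- rnorm(48)
  for (T in c(16, 21.3, 24, 37)) {
    f <- fit_harmonics(t, y, T, 3)
    expect_lte(f$rss, sum((y - mean(y))^2) + 1e-9)
  }
})

test_that("rank-deficient design raises a degenerate-fit error", {
  t <- seq(0, 2, length.out = 20)
  y <- rnorm(20)
  # period vastly longer than the span: cos ~ constant, collinear with intercept
  expect_error(fit_harmonics(t, y, 1e8, 2), "rank-deficient|degenerate")
})

test_that("estimate_period recovers constructed truth", {
  tr <- simulate_trace(noiseless_params(period = 24, phase = 6), seed = 1)
  f <- estimate_period(tr$time_h, tr$lum)
  expect_equal(f$period, 24, tolerance = 0.05)
  expect_equal(f$phase, 6, tolerance = 0.1)
  expect_true(f$rhythmic)

  tr2 <- simulate_trace(noiseless_params(period = 31.7, phase = 3), seed = 1)
  f2 <- estimate_period(tr2$time_h, tr2$lum)
  expect_equal(f2$period, 31.7, tolerance = 0.1)
})

test_that("noiseless damped cosines are recovered across the circadian range", {
  for (T in c(20, 24, 28, 32)) {
    p <- trace_params(noise_sd = 0, damping_rate = 0.01, period = T,
                      phase = 5, duration = 120)
    tr <- simulate_trace(p, seed = 1)
    f <- estimate_period(tr$time_h, tr$lum, grid_step = 0.05)
    expect_equal(f$period, T, tolerance = 0.1)   # within 2x grid_step
  }
})

test_that("period estimate is invariant to offset and positive rescaling", {
  tr <- simulate_trace(trace_params(noise_sd = 60, period = 26), seed = 8)
  f0 <- estimate_period(tr$time_h, tr$lum)
  f1 <- estimate_period(tr$time_h, 3.7 * tr$lum + 1e4)
  expect_equal(f0$period, f1$period, tolerance = 1e-9)
  expect_equal(3.7 * f0$amplitude, f1$amplitude, tolerance = 1e-6)
})

test_that("time-reversed pure cosine gives the same period", {
  t <- 0:96
  y <- 1000 + 400 * cos(2 * pi * (t - 3) / 26)
  f_fwd <- estimate_period(t, y, burn_in = 0)
  f_rev <- estimate_period(t, rev(y), burn_in = 0)
  expect_equal(f_fwd$period, f_rev$period, tolerance = 1e-6)
})

test_that("constant traces come back arrhythmic, not as an error", {
  t <- 0:48
  f <- estimate_period(t, rep(1000, 49))
  expect_false(f$rhythmic)
  expect_true(is.na(f$period))
  expect_error(estimate_phase(f), "arrhythmic")
})

test_that("estimate_phase wraps and shifts as expected", {
  t <- seq(0, 96, 0.5)
  circ_dist <- function(a, b, T) {
    d <- abs(a - b) %% T
    min(d, T - d)
  }
  f0 <- estimate_period(t, cos(2 * pi * t / 24), burn_in = 0)
  expect_lt(circ_dist(estimate_phase(f0), 0, 24), 0.01)
  f6 <- estimate_period(t, cos(2 * pi * (t - 6) / 24), burn_in = 0)
  expect_lt(circ_dist(estimate_phase(f6), 6, 24), 0.01)
  # wrap invariance: shifting the trace by a full period changes nothing
  f30 <- estimate_period(t, cos(2 * pi * (t - 30) / 24), burn_in = 0)
  expect_lt(circ_dist(estimate_phase(f30), estimate_phase(f6), 24), 0.01)
})

test_that("batched fit_rhythms matches the single-trace estimator", {
  sim <- simulate_plate(trace_params(noise_sd = 80), seed = 5, n_replicates = 4)
  fits <- fit_rhythms(sim)
  for (w in unique(sim$well)) {
    g <- sim[sim$well == w, ]
    f <- estimate_period(g$time_h, g$lum)
    expect_equal(fits$period_h[fits$well == w], f$period, tolerance = 1e-9)
    expect_equal(fits$phase_h[fits$well == w], f$phase, tolerance = 1e-9)
  }
})

test_that("compare_periods matches Welch and is antisymmetric", {
  a <- c(24.1, 23.9, 24.0, 24.2)
  b <- c(26.0, 26.3, 25.8, 26.1)
  cmp <- compare_periods(a, b)
  ref <- t.test(b, a, var.equal = FALSE)
  expect_equal(cmp$mean_difference, mean(b) - mean(a))
  expect_equal(cmp$p_value, ref$p.value)
  flipped <- compare_periods(b, a)
  expect_equal(flipped$mean_difference, -cmp$mean_difference)
  expect_equal(flipped$p_value, cmp$p_value)
})

test_that("identical groups give zero difference and p = 1", {
  g <- c(24.0, 24.3, 23.8, 24.1)
  cmp <- compare_periods(g, g)
  expect_equal(cmp$mean_difference, 0)
  expect_equal(cmp$p_value, 1)
})

test_that("zero-variance groups report the difference with undefined p", {
  cmp <- compare_periods(rep(24, 4), rep(26, 4))
  expect_equal(cmp$mean_difference, 2)
  expect_true(is.na(cmp$p_value))
})

test_that("compare_periods rejects groups with under two rhythmic fits", {
  expect_error(compare_periods(24, c(25, 26)), "insufficient replicates")
})

test_that("compare_periods type-I error is calibrated under the null", {
  set.seed(99)
  n_sim <- 4000
  hits <- 0L
  for (i in seq_len(n_sim)) {
    a <- rnorm(8, 24, 0.3)
    b <- rnorm(8, 24, 0.3)
    if (compare_periods(a, b)$p_value < 0.05) hits <- hits + 1L
  }
  rate <- hits / n_sim
  expect_gt(rate, 0.035)
  expect_lt(rate, 0.065)
})
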