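test_that("exact lines are recovered with zero residual", {
  t <- seq(0, 50, by = 5)
  f <- fit_line(t, 3.8 - 0.02 * t)
  expect_equal(f$slope1, -0.02, tolerance = 1e-12)
  expect_equal(f$intercept, 3.8, tolerance = 1e-12)
  expect_equal(f$rss, 0, tolerance = 1e-20)
})

test_that("fixed-intercept slope matches its closed form", {
  set.seed(4)
  for (i in 1:20) {
    t <- sort(runif(15, 0, 60))
    y <- 3.8 - 0.05 * t + rnorm(15, 0, 0.1)
    c0 <- 3.8
    f <- fit_line(t, y, fixed_intercept = c0)
    expect_equal(f$slope1, sum(t * (y - c0)) / sum(t^2), tolerance = 1e-10)
    expect_equal(f$intercept, c0)
  }
})

test_that("degenerate line inputs are rejected", {
  expect_error(fit_line(c(0, 1), c(1, 2)), "3 points")
  expect_error(fit_line(c(2, 2, 2), c(1, 2, 3)), "Zero time variance")
})

test_that("noiseless two-slope data recover all segmented parameters", {
  t <- seq(0, 60, by = 2)
  y <- piecewise_y(t, a = 3.8, b1 = -0.1, b2 = -0.01, psi = 20)
  f <- fit_segmented(t, y)
  expect_equal(f$intercept, 3.8, tolerance = 1e-6)
  expect_equal(f$slope1, -0.1, tolerance = 1e-6)
  expect_equal(f$slope2, -0.01, tolerance = 1e-6)
  expect_equal(f$breakpoint, 20, tolerance = 1e-6)
  expect_lt(f$rss, 1e-12)
})

test_that("a pure line leaves the segmented fit degenerate but harmless", {
  t <- seq(0, 60, by = 2)
  y <- 3.8 - 0.03 * t
  sf <- fit_line(t, y)
  gf <- fit_segmented(t, y)
  expect_equal(gf$rss, sf$rss, tolerance = 1e-10)
  expect_equal(gf$slope1, -0.03, tolerance = 1e-6)
  expect_equal(gf$slope2, -0.03, tolerance = 1e-6)
})

test_that("segments meet continuously at the breakpoint", {
  set.seed(12)
  for (i in 1:10) {
    t <- seq(0, 100, by = 4)
    y <- piecewise_y(t, 3.8, -0.08, -0.005, 35) + rnorm(length(t), 0, 0.05)
    f <- fit_segmented(t, y)
    left <- f$intercept + f$slope1 * f$breakpoint
    right <- predict(f, f$breakpoint + 1e-12)
    expect_lt(abs(left - right), 1e-9)
  }
})

test_that("adding a breakpoint never increases the RSS", {
  set.seed(31)
  for (i in 1:15) {
    t <- sort(runif(sample(10:25, 1), 0, 120))
    y <- 3.8 - runif(1, 0.005, 0.05) * t + rnorm(length(t), 0, 0.1)
    expect_lte(fit_segmented(t, y)$rss, fit_line(t, y)$rss + 1e-10)
  }
})

test_that("profiled breakpoint matches the brute-force oracle", {
  set.seed(99)
  for (i in 1:50) {
    n <- sample(12:30, 1)
    t <- sort(runif(n, 0, 100)); t <- t - t[1]
    psi <- runif(1, t[4], t[n - 3])
    y <- piecewise_y(t, 3.8, -runif(1, 0.02, 0.1),
                     -runif(1, 0.001, 0.02), psi) + rnorm(n, 0, 0.05)
    f <- fit_segmented(t, y)
    b <- brute_force_segmented(t, y)
    expect_lt(abs(f$breakpoint - b$psi), b$step + 1e-9)
    expect_lt(f$rss, b$rss + 1e-8)
  }
})

test_that("manual breakpoints are honored and validated", {
  t <- seq(0, 60, by = 2)
  y <- piecewise_y(t, 3.8, -0.1, -0.01, 20)
  f <- fit_segmented(t, y, psi = 25)
  expect_equal(f$breakpoint, 25)
  expect_true(f$psi_manual)
  expect_error(fit_segmented(t, y, psi = 1), "min_seg")
})

test_that("too few points for two segments is an error", {
  expect_error(fit_segmented(0:4, c(5, 4, 3, 2, 1)), "at least 6")
})

test_that("strong two-phase data select the segmented model", {
  set.seed(7)
  t <- seq(0, 195, by = 5)
  y <- piecewise_y(t, 3.8, -0.05, -0.005, 30) + rnorm(length(t), 0, 0.04)
  ch <- select_model(fit_line(t, y), fit_segmented(t, y))
  expect_equal(ch$model, "segmented")
  expect_lt(ch$p_value, 0.05)
})

test_that("a perfect line at minimal n stays single", {
  t <- seq(0, 25, by = 5)
  y <- 3.8 - 0.02 * t
  ch <- select_model(fit_line(t, y), fit_segmented(t, y))
  expect_equal(ch$model, "single")
})

test_that("segmented fits with a rising segment are never selected", {
  # V-shaped trace: F-test fires, but the rise disqualifies it
  t <- seq(0, 100, by = 5)
  y <- piecewise_y(t, 3.8, -0.05, 0.02, 50)
  ch <- select_model(fit_line(t, y), fit_segmented(t, y))
  expect_equal(ch$model, "single")
  expect_false(ch$slopes_negative)
})

test_that("null traces trigger the segmented model at about the alpha rate", {
  t <- seq(0, 195, by = 5)
  n_seg <- 0
  for (s in 1:200) {
    set.seed(s)
    y <- 3.8 - 0.01 * t + rnorm(length(t), 0, 0.05)
    ch <- select_model(fit_line(t, y), fit_segmented(t, y), alpha = 0.05)
    if (ch$model == "segmented") n_seg <- n_seg + 1
  }
  rate <- n_seg / 200
  expect_gte(rate, 0.005)
  expect_lte(rate, 0.105)
})

test_that("NPQ rise is excised and the signal re-anchored to the depth", {
  # rise for ~30 min then decline
  t <- seq(0, 195, by = 5)
  y <- piecewise_y(t, 2.8, 0.03, -0.012, 30)
  cn <- correct_npq_rise(t, y, depth_mm = 3.8)
  expect_true(cn$npq_corrected)
  expect_equal(cn$rise_end_min, 30, tolerance = 1)
  # extrapolated t=0 value of the corrected sinking line equals depth
  f <- fit_line(cn$times, cn$depth_signal)
  expect_equal(f$intercept, 3.8, tolerance = 1e-6)
})

test_that("monotone traces pass through or error as appropriate", {
  t <- seq(0, 100, by = 5)
  declining <- 3.8 - 0.02 * t
  cn <- correct_npq_rise(t, declining)
  expect_false(cn$npq_corrected)
  expect_equal(cn$depth_signal, declining)

  rising <- 1 + 0.02 * t
  expect_error(correct_npq_rise(t, rising), "no sinking phase")
})

test_that("amplitudes implement the fractional signal drop and sum to 1", {
  t <- seq(0, 60, by = 2)
  y <- piecewise_y(t, 3.8, -0.1, -0.01, 20)
  f <- fit_segmented(t, y)
  amp <- amplitudes(f)
  expect_equal(amp[["amplitude1"]], (3.8 - 1.8) / 3.8, tolerance = 1e-6)
  expect_equal(sum(amp), 1, tolerance = 1e-9)

  fl <- fit_line(t, 3.8 - 0.02 * t)
  expect_equal(amplitudes(fl)[["amplitude1"]], 1)
  expect_true(is.na(amplitudes(fl)[["amplitude2"]]))
})

test_that("amplitude conservation holds across random segmented fits", {
  set.seed(17)
  for (i in 1:25) {
    t <- seq(0, 150, by = 5)
    # physical traces: the fitted signal stays positive over the window
    b1 <- runif(1, 0.02, 0.1)
    psi <- runif(1, 20, min(120, 0.9 * 3.8 / b1))
    y_psi <- 3.8 - b1 * psi
    b2 <- runif(1, 0.1, 0.9) * y_psi / (max(t) - psi)
    y <- piecewise_y(t, 3.8, -b1, -b2, psi) + rnorm(length(t), 0, 0.04)
    amp <- amplitudes(fit_segmented(t, y))
    expect_equal(sum(amp), 1, tolerance = 1e-9)
    expect_gte(amp[["amplitude1"]], 0)
    expect_lte(amp[["amplitude1"]], 1)
  }
})

test_that("rates convert slopes and block rising fits", {
  t <- seq(0, 60, by = 2)
  seg <- fit_segmented(t, piecewise_y(t, 3.8, -0.0424, -0.0125, 20))
  r <- extract_rates(seg)
  expect_equal(r$rate1_m_per_day, 0.0424 * 1.44, tolerance = 1e-6)
  expect_equal(r$rate1_m_per_day, 0.061, tolerance = 1e-3)
  expect_equal(r$rate2_m_per_day, 0.018, tolerance = 1e-3)

  single <- fit_line(t, rep(3.8, length(t)))
  expect_equal(extract_rates(single)$rate1_m_per_day, 0, tolerance = 1e-9)
  expect_true(is.na(extract_rates(single)$rate2_m_per_day))

  rising <- fit_line(t, 1 + 0.02 * t)
  expect_error(extract_rates(rising), "rising")
})

test_that("noiseless forward-model traces recover the rate within 20%", {
  # fit window chosen so t*s <= 0.2: the sqrt/linear approximation bias is
  # bounded, and the bound itself is what this asserts
  for (s in c(0.002, 0.005, 0.01)) {
    t <- seq(0, 0.2 / s, length.out = 30)
    ds <- depth_transform(forward_scaled(t, s), 3.8)
    f <- fit_line(t, ds)
    rate <- slope_to_rate(abs(f$slope1))
    nominal <- 3.8 * s * 1.44
    expect_lt(abs(rate - nominal) / nominal, 0.2)
  }
})

test_that("tidy and glance expose fit terms and summaries", {
  t <- seq(0, 60, by = 2)
  f <- fit_segmented(t, piecewise_y(t, 3.8, -0.1, -0.01, 20))
  td <- tidy(f)
  expect_equal(td$term, c("intercept", "slope1", "slope2", "breakpoint"))
  expect_equal(td$estimate[4], 20, tolerance = 1e-6)
  gl <- glance(f)
  expect_equal(gl$model, "segmented")
  expect_equal(gl$n, length(t))
})
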