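test_that("ROI HRF is the pointwise channel mean", {
  t <- seq(0, 1, length.out = 100)
  ch1 <- oxy_channel("a", "mPFC", t, -t / 3)
  expect_equal(roi_hrf(list(ch1)), t)
  ch2 <- oxy_channel("b", "mPFC", -t, t / 3)
  expect_equal(roi_hrf(list(ch1, ch2)), rep(0, 100))
  ch3 <- oxy_channel("c", "mPFC", 2 * t, -t)
  expect_equal(roi_hrf(list(ch1, ch3)), 1.5 * t)
  expect_equal(roi_hrf(list(ch1, ch3), "hhb"), (-t / 3 - t) / 2)
  expect_error(roi_hrf(list()), class = "oxydrift_roi_empty")
})

test_that("decline point recovers an analytic maximum", {
  u <- seq(0, 1, length.out = 2000)
  dp <- decline_point(-(u - 0.8)^2)
  expect_equal(dp$d_pct, 80, tolerance = 0.11)  # grid resolution is 0.1
  expect_false(dp$monotonic)
  # strictly increasing line: maximum at the right edge, flagged monotonic
  dp2 <- decline_point(u)
  expect_equal(dp2$d_pct, 100)
  expect_true(dp2$monotonic)
  expect_error(decline_point(c(1, 2, 3), degree = 5), class = "oxydrift_short")
})

test_that("decline point is invariant to affine amplitude rescaling", {
  u <- seq(0, 1, length.out = 1500)
  hrf <- withr::with_seed(1, -(u - 0.6)^2 + 0.02 * rnorm(1500))
  d0 <- decline_point(hrf)$d_pct
  expect_equal(decline_point(5 * hrf + 7)$d_pct, d0)
  expect_equal(decline_point(0.1 * hrf - 3)$d_pct, d0)
})

test_that("activation slope is the OLS slope up to D", {
  fs <- 10
  t <- (0:999) / fs
  expect_equal(activation_slope(0.3 * t + 2, fs, 100), 0.3, tolerance = 1e-9)
  expect_equal(activation_slope(rep(5, 1000), fs, 100), 0)
  # ramp then fall: the fit over the first half sees only the ramp
  ramp <- c(0.4 * t[1:500], 0.4 * t[500] - 0.8 * (t[501:1000] - t[500]))
  expect_equal(activation_slope(ramp, fs, 50), 0.4, tolerance = 1e-9)
  expect_error(activation_slope(t, fs, 0.01), class = "oxydrift_short")
})

test_that("beta scales linearly with HRF amplitude", {
  fs <- 10
  hrf <- withr::with_seed(2, 0.2 * (0:999) / fs + rnorm(1000, 0, 0.1))
  b <- activation_slope(hrf, fs, 70)
  expect_equal(activation_slope(3 * hrf, fs, 70), 3 * b, tolerance = 1e-9)
})

test_that("delta value matches closed-form window means", {
  fs <- 10
  expect_equal(delta_value(rep(2, 1000), fs), 0)
  # line from 0 to 1 over 100 s: mean(last 5 s) - mean(first 5 s) ~ 0.95
  lin <- seq(0, 1, length.out = 1000)
  expect_equal(delta_value(lin, fs), 0.95, tolerance = 0.005)
  expect_lt(delta_value(rev(lin), fs), 0)
  expect_error(delta_value(lin[1:80], fs), class = "oxydrift_short")
})

test_that("two-segment fit recovers an exact kink and nests the line", {
  fs <- 10
  t <- (0:999) / fs
  kink <- 0.6 * t[1000]
  y <- ifelse(t <= kink, 0.5 * t, 0.5 * kink - 0.3 * (t - kink))
  sf <- two_segment_fit(y, fs)
  expect_lt(abs(sf$breakpoint_s - kink), 1.0)   # within one grid step
  expect_lt(sf$rss, 1e-6)
  expect_equal(sf$slope_pre, 0.5, tolerance = 1e-3)
  expect_equal(sf$slope_post, -0.3, tolerance = 1e-3)
  # pure line: the second slope vanishes and RSS matches the straight fit
  yl <- withr::with_seed(3, 2 + 0.1 * t + rnorm(1000, 0, 0.2))
  sfl <- two_segment_fit(yl, fs)
  line_rss <- sum(resid(lm(yl ~ t))^2)
  expect_lte(sfl$rss, line_rss + 1e-9)
  expect_lt(abs(sfl$slope_post - sfl$slope_pre), 0.1)
  expect_error(two_segment_fit(rep(1, 100), fs), class = "oxydrift_degenerate")
})

test_that("two-segment RSS never exceeds the single-line RSS", {
  fs <- 10
  t <- (0:499) / fs
  for (s in 1:5) {
    y <- withr::with_seed(s, sin(2 * pi * 0.02 * t) + rnorm(500, 0, 0.3))
    sf <- two_segment_fit(y, fs)
    expect_lte(sf$rss, sum(resid(lm(y ~ t))^2) + 1e-9)
  }
})

test_that("information criteria follow the stated parameter counts", {
  u <- seq(0, 1, length.out = 500)
  hrf <- withr::with_seed(4, -(u - 0.6)^2 + rnorm(500, 0, 0.05))
  dp <- decline_point(hrf)
  sf <- two_segment_fit(hrf, 10)
  mc <- model_compare(dp$fit, sf)
  n <- 500
  expect_equal(mc$aic[1], n * log(dp$fit$rss / n) + 2 * dp$fit$k,
               tolerance = 1e-9)
  expect_equal(dp$fit$k, dp$fit$degree + 2L)
  expect_equal(mc$bic[2], n * log(sf$rss / n) + 5 * log(n), tolerance = 1e-9)
  # equal RSS and k implies equal criteria
  f1 <- list(rss = 2, n = 100, k = 5)
  expect_equal(model_compare(f1, f1)$aic[1], model_compare(f1, f1)$aic[2])
  # perfect fit flags the -Inf sentinel
  f0 <- list(rss = 0, n = 100, k = 5)
  mc0 <- model_compare(f0, f1)
  expect_true(mc0$degenerate[1])
  expect_equal(mc0$aic[1], -Inf)
})

test_that("AIC prefers the generative model family", {
  fs <- 10
  t <- (0:599) / fs
  kink <- 0.7 * t[600]
  seg_wins <- 0; poly_wins <- 0
  for (s in 1:60) {
    y_seg <- withr::with_seed(s, ifelse(t <= kink, 0.3 * t,
                                        0.3 * kink - 0.5 * (t - kink)) +
                                 rnorm(600, 0, 0.5))
    dp <- decline_point(y_seg); sf <- two_segment_fit(y_seg, fs)
    mc <- model_compare(dp$fit, sf)
    if (mc$aic[2] < mc$aic[1]) seg_wins <- seg_wins + 1
    y_arch <- withr::with_seed(s + 500, sin(pi * t / t[600]) + rnorm(600, 0, 0.1))
    dp2 <- decline_point(y_arch); sf2 <- two_segment_fit(y_arch, fs)
    mc2 <- model_compare(dp2$fit, sf2)
    if (mc2$aic[1] < mc2$aic[2]) poly_wins <- poly_wins + 1
  }
  expect_gte(seg_wins / 60, 0.9)
  expect_gte(poly_wins / 60, 0.9)
})

test_that("cohort-level criterion comparison matches the paired t oracle", {
  a <- withr::with_seed(5, rnorm(40, -100, 3))
  b <- a - withr::with_seed(6, rnorm(40, 0.8, 1))
  cc <- cohort_model_compare(a, b, a + 1, b + 1)
  tt <- t.test(a, b, paired = TRUE)
  expect_equal(cc$t[1], unname(tt$statistic), tolerance = 1e-12)
  expect_equal(cc$p[1], tt$p.value, tolerance = 1e-12)
  d <- a - b
  expect_equal(cc$cohens_d[1], mean(d) / sd(d), tolerance = 1e-12)
  # shifting both criteria equally leaves the paired test unchanged
  expect_equal(cc$t[2], cc$t[1], tolerance = 1e-12)
})

test_that("analyze_recording ties the chain together on planted truth", {
  g <- generate_recording(signal_spec(trend = trend_spec("quadratic_peak",
                                                         peak_fraction = 0.7)),
                          rois = c(mPFC = 3), seed = 21)
  qc <- qc_recording(g$recording, g$annotations, reference_hr = 150)
  m <- analyze_recording(g$recording, g$annotations, ppg = g$ppg, qc = qc)
  expect_equal(nrow(m), 1)
  expect_equal(m$roi, "mPFC")
  expect_lt(abs(m$d_pct - 70), 5)
  expect_gt(m$beta, 0)
  expect_true(is.finite(m$aic_poly) && is.finite(m$aic_seg))
  expect_true(m$d_pct >= 0 && m$d_pct <= 100)
  expect_true(m$breakpoint_pct > 0 && m$breakpoint_pct < 100)
})
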