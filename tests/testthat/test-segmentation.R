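test_that("the GLR statistic matches a straight-from-formula oracle", {
  set.seed(42)
  w <- rnorm(20)
  mle_var <- function(v) max(mean(v^2) - mean(v)^2, 1e-12)
  for (k in c(2, 8, 15)) {
    oracle <- 20 * log(mle_var(w)) - k * log(mle_var(w[1:k])) -
      (20 - k) * log(mle_var(w[(k + 1):20]))
    expect_equal(glr_statistic(w, k), oracle, tolerance = 1e-12)
    expect_equal(glr_scan(w, min_side = 2)[k], oracle, tolerance = 1e-12)
  }
  expect_error(glr_statistic(w, 1, min_side = 2), "min_side")
})

test_that("the scan peaks at the true split of a step window", {
  set.seed(1)
  w <- c(rep(0, 20), rep(5, 20)) + rnorm(40, 0, 1e-3)
  sc <- glr_scan(w, min_side = 2)
  expect_equal(which.max(sc), 20L)
  expect_true(all(sc[20] > sc[setdiff(2:38, 20)]))
})

test_that("the statistic stays below calibrated thresholds on null data", {
  th <- test_thresholds()
  set.seed(10)
  vals <- replicate(50, max(glr_scan(rnorm(200), min_side = 5),
                            na.rm = TRUE))
  h200 <- approx(th$t, th$h, xout = 200, rule = 2)$y
  # under constant hazard 1/500 over ~190 admissible steps, most windows
  # never cross; a handful of exceedances among 50 windows is expected
  expect_lt(mean(vals > h200), 0.3)
})

test_that("calibration is self-consistent: mean run length near ARL0", {
  # measured with the same burn-in the calibration assumes (detection
  # from 2 * min_side observations), so the run-length target is ARL0
  th <- test_thresholds()
  rl <- null_run_lengths(th, n_streams = 400, startup = 10,
                         min_side = 5, cap = 6000, seed = 31)
  expect_lt(abs(mean(rl$run_length) - 500) / 500, 0.15)
})

test_that("thresholds weakly increase with ARL0 and flatten at large t", {
  th_lo <- test_thresholds()                      # arl0 = 500
  th_hi <- memo("th1000", function() {
    calibrate_thresholds(cpm_params(arl0 = 1000, startup = 100,
                                    calibration_reps = 1000, seed = 7),
                         horizon = 3000)
  })
  tt <- seq(10, max(th_lo$t))
  h_lo <- approx(th_lo$t, th_lo$h, xout = tt, rule = 2)$y
  h_hi <- approx(th_hi$t, th_hi$h, xout = tt, rule = 2)$y
  # Monte-Carlo tolerance: a doubled ARL0 shifts the curve up by ~log(2)
  # on the exponential-tail scale
  expect_true(all(h_hi >= h_lo - 0.3))
  expect_gt(mean(h_hi - h_lo), 0.5)
  # beyond the stationary onset the curve no longer grows
  late <- approx(th_lo$t, th_lo$h, xout = c(500, 1000, 2000), rule = 2)$y
  expect_true(all(diff(late) <= 1e-9))
})

test_that("a noiseless constant trace yields a single segment", {
  tr <- accel_trace((0:999) / 140, rep(0, 1000), rep(0, 1000),
                    rep(1, 1000))
  ss <- segment_stream(tr, cpm_params(arl0 = 500, startup = 100,
                                      calibration_reps = 1000, seed = 7),
                       thresholds = test_thresholds())
  expect_equal(nrow(ss$segments), 1L)
  expect_identical(ss$boundaries, c(0L, 1000L))
})

test_that("a trace shorter than startup degrades to one flagged segment", {
  tr <- accel_trace((0:49) / 140, rnorm(50), rnorm(50), rnorm(50))
  expect_warning(
    ss <- segment_stream(tr, cpm_params(arl0 = 500, startup = 100,
                                        calibration_reps = 1000, seed = 7)),
    "single segment")
  expect_equal(nrow(ss$segments), 1L)
})

test_that("a 4-SD mean shift is found accurately and quickly", {
  p <- cpm_params(arl0 = 500, startup = 100, calibration_reps = 1000,
                  seed = 7)
  th <- test_thresholds()
  localized <- 0L
  detected_fast <- 0L
  set.seed(99)
  n_runs <- 50
  for (r in seq_len(n_runs)) {
    x <- c(rnorm(2000), rnorm(500, 4))
    tr <- accel_trace((0:2499) / 140, x, x, x)
    ss <- segment_stream(tr, p, thresholds = th)
    b <- ss$boundaries[-c(1, length(ss$boundaries))]
    # detections cluster around a strong change (the delay window is
    # re-scanned after every restart), so "localized" means at least one
    # boundary lands within +/-25 samples of the truth
    if (any(abs(b - 2000) <= 25)) localized <- localized + 1L
    det <- b + ss$detection_delays
    if (any(abs(b - 2000) <= 25 & det <= 2200))
      detected_fast <- detected_fast + 1L
  }
  expect_gte(localized / n_runs, 0.9)
  expect_gte(detected_fast / n_runs, 0.9)
})

test_that("segmentation tiles the trace and is bit-identical under a seed", {
  bm <- small_benchmark()
  tr <- bm[[1]]$trace
  p <- cpm_params(arl0 = 500, calibration_reps = 1000, seed = 7,
                  startup = 140)
  th <- test_thresholds()
  s1 <- segment_stream(tr, p, thresholds = th)
  s2 <- segment_stream(tr, p, thresholds = th)
  expect_identical(s1, s2)
  expect_equal(s1$segments$start[1], 0L)
  expect_equal(s1$segments$end[nrow(s1$segments)], n_samples(tr))
  expect_true(all(s1$segments$start[-1] ==
                    s1$segments$end[-nrow(s1$segments)]))
  expect_true(all(s1$detection_delays >= 0L))
})

test_that("behaviour transitions are recovered within half a second", {
  sched <- behavior_schedule(c("sitting", "flapping", "soaring"),
                             c(5, 5, 5), 140)
  g <- generate_trace(sched, behavior_params(seed = 21))
  p <- cpm_params(arl0 = 500, startup = 140, calibration_reps = 1000,
                  seed = 7)
  ss <- segment_stream(g$trace, p, thresholds = test_thresholds())
  b <- ss$boundaries[-c(1, length(ss$boundaries))]
  for (truth in c(5 * 140, 10 * 140)) {
    expect_true(any(abs(b - truth) <= 0.5 * 140),
                info = sprintf("transition at sample %d", truth))
  }
})
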