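test_that("static acceleration reproduces constants and the identity window", {
  expect_equal(static_acceleration(rep(2.5, 100), 140), rep(2.5, 100))
  v <- rnorm(50)
  expect_equal(static_acceleration(v, 140, odba_params(window_s = 1 / 140)),
               v)
})

test_that("the running mean attenuates a sine by the closed-form gain", {
  rate <- 140
  f <- 4
  tt <- (0:(10 * rate - 1)) / rate
  v <- sin(2 * pi * f * tt)
  w <- 2 * floor(round(1 * rate) / 2) + 1      # effective odd window
  gain <- sin(pi * f * w / rate) / (w * sin(pi * f / rate))
  sa <- static_acceleration(v, rate)
  core <- (w + 1):(length(v) - w)              # away from edge truncation
  expect_equal(max(abs(sa[core])), abs(gain), tolerance = 1e-2)
  expect_lt(max(abs(sa[core])), 0.05)          # near-zero: 4 Hz >> 1 Hz window
})

test_that("ODBA is zero for constants, homogeneous of degree one", {
  tr <- accel_trace((0:279) / 140, rep(0.3, 280), rep(-0.1, 280),
                    rep(1, 280))
  expect_equal(odba(tr), 0)
  g <- generate_trace(behavior_schedule("flapping", 2, 140),
                      behavior_params(seed = 4))
  tr1 <- g$trace
  tr2 <- accel_trace(tr1$time, 2 * tr1$x, 2 * tr1$y, 2 * tr1$z)
  expect_equal(odba(tr2), 2 * odba(tr1), tolerance = 1e-12)
})

test_that("ODBA of a pure sine matches a direct numeric oracle", {
  rate <- 140
  tt <- (0:(10 * rate - 1)) / rate
  z <- sin(2 * pi * 4 * tt)
  tr <- accel_trace(tt, rep(0, length(tt)), rep(0, length(tt)), z)
  # oracle: subtract the running mean directly and average |residual|
  sa <- static_acceleration(z, rate)
  expect_equal(odba(tr), mean(abs(z - sa)), tolerance = 1e-12)
  # away from the truncated edges the residual is (1 - gain) * sin, so
  # the mean absolute dynamic is (2/pi) * (1 - gain)
  w <- 2 * floor(round(rate) / 2) + 1
  gain <- sin(pi * 4 * w / rate) / (w * sin(pi * 4 / rate))
  core <- (w + 1):(length(z) - w)
  expect_equal(mean(abs(z - sa)[core]), (2 / pi) * (1 - gain),
               tolerance = 0.01)
})

test_that("segment statistics reproduce closed forms on a ramp and sine", {
  rate <- 140
  tt <- (0:279) / rate
  x <- 0.5 * tt
  z <- sin(2 * pi * 4 * tt)
  tr <- accel_trace(tt, x, x, z)
  f <- segment_features(tr, 0, 280)
  expect_equal(unname(f["trend_x"]), 0.5, tolerance = 1e-9)
  expect_equal(unname(f["sd_x"]), sd(x), tolerance = 1e-12)
  expect_equal(unname(f["domfreq_z"]), 4)
  expect_equal(unname(f["corr_xy"]), 1)
  expect_equal(unname(f["mean_x"]), mean(x))
  expect_equal(unname(f["min_x"]), 0)
  expect_equal(unname(f["max_x"]), max(x))
})

test_that("skewness and kurtosis use population moment conventions", {
  set.seed(8)
  v <- rnorm(5000)
  tr <- accel_trace(seq_along(v) / 140, v, v, v)
  f <- segment_features(tr, 0, length(v))
  # kurtosis is non-excess: ~3 for a normal sample
  expect_equal(unname(f["kurt_x"]), 3, tolerance = 0.15)
  expect_equal(unname(f["skew_x"]), 0, tolerance = 0.1)
  d <- v - mean(v)
  expect_equal(unname(f["kurt_x"]), mean(d^4) / mean(d^2)^2,
               tolerance = 1e-12)
})

test_that("feature vectors have exactly the 28 registry statistics", {
  g <- generate_trace(behavior_schedule(c("soaring", "flapping"), c(1, 1),
                                        140), behavior_params(seed = 6))
  f <- segment_features(g$trace, 10, 150)
  expect_length(feature_names(), 28L)
  expect_setequal(setdiff(names(f), "n_samples"), feature_names())
  expect_true(all(is.finite(f)))
  expect_lte(f["min_x"], f["mean_x"])
  expect_lte(f["mean_x"], f["max_x"])
  expect_gte(f["sd_x"], 0)
  expect_true(all(abs(f[c("corr_xy", "corr_xz", "corr_yz")]) <= 1))
  expect_gte(f["odba"], 0)
})

test_that("reversing a segment negates the trend and keeps domfreq", {
  g <- generate_trace(behavior_schedule("flapping", 2, 140),
                      behavior_params(seed = 13))
  tr <- g$trace
  rev_tr <- accel_trace(tr$time, rev(tr$x), rev(tr$y), rev(tr$z))
  f1 <- segment_features(tr, 0, 280)
  f2 <- segment_features(rev_tr, 0, 280)
  expect_equal(unname(f2["trend_z"]), -unname(f1["trend_z"]),
               tolerance = 1e-9)
  expect_equal(f2["domfreq_z"], f1["domfreq_z"])
  same <- c("mean_x", "min_z", "max_z", "sd_z", "kurt_z", "corr_xz")
  expect_equal(f2[same], f1[same], tolerance = 1e-9)
})

test_that("segment ODBA equals the sum of per-axis mean absolute dynamics", {
  g <- generate_trace(behavior_schedule(c("flapping", "soaring"), c(1, 1),
                                        140), behavior_params(seed = 17))
  tr <- g$trace
  f <- segment_features(tr, 20, 160)
  per_axis <- vapply(c("x", "y", "z"), function(a) {
    dyn <- tr[[a]] - static_acceleration(tr[[a]], tr$nominal_rate_hz)
    mean(abs(dyn[21:160]))
  }, 0)
  expect_equal(unname(f["odba"]), sum(per_axis), tolerance = 1e-12)
})

test_that("all features are finite on every benchmark segment", {
  segs <- small_pipeline()
  expect_true(all(is.finite(as.matrix(segs[, feature_names()]))))
  expect_gte(min(segs$n_samples), 5)
})
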