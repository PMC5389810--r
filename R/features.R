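#' ODBA parameters
#'
#' @param window_s running-mean window in seconds used to estimate the
#'   static (gravitational) component of each channel.  Default 1 s, a
#'   standard choice for large birds whose wingbeat period is well under a
#'   second.
#' @return An object of class `odba_params`.
#' @export
odba_params <- function(window_s = 1.0) {
  if (!is.finite(window_s) || window_s <= 0) stop("window_s must be > 0")
  structure(list(window_s = window_s), class = "odba_params")
}

#' Static (gravitational) component of one channel
#'
#' Centred running mean over `round(window_s * rate_hz)` samples.  Near the
#' edges the window is truncated symmetrically (equal counts on both
#' sides), so the output stays centred and has the same length as the
#' input.  An even window count is widened by one so a centre sample
#' exists.
#'
#' @param channel numeric vector of raw acceleration.
#' @param rate_hz sampling rate in Hz.
#' @param params an [odba_params()].
#' @return Numeric vector, same length as `channel`.
#' @export
static_acceleration <- function(channel, rate_hz, params = odba_params()) {
  n <- length(channel)
  if (n == 0L) stop("empty channel")
  w <- round(params$window_s * rate_hz)
  if (w <= 1L) return(channel)
  half <- floor(w / 2)
  idx <- seq_len(n)
  r <- pmin(half, idx - 1L, n - idx)
  cs <- c(0, cumsum(channel))
  (cs[idx + r + 1L] - cs[idx - r]) / (2L * r + 1L)
}

#' Per-sample dynamic body acceleration and ODBA
#'
#' The dynamic component is raw minus static per axis; the per-sample
#' overall dynamic body acceleration (ODBA) is the sum of the absolute
#' dynamic components of the three axes.  Over a window or segment the
#' reported ODBA is the mean of the per-sample values, so it measures
#' intensity rather than confounding it with duration.
#'
#' @param trace an [accel_trace()].
#' @param params an [odba_params()].
#' @return Numeric vector of per-sample ODBA, length `n_samples(trace)`.
#' @export
odba_series <- function(trace, params = odba_params()) {
  stopifnot(inherits(trace, "accel_trace"))
  r <- trace$nominal_rate_hz
  abs(trace$x - static_acceleration(trace$x, r, params)) +
    abs(trace$y - static_acceleration(trace$y, r, params)) +
    abs(trace$z - static_acceleration(trace$z, r, params))
}

#' ODBA of a sample window
#'
#' @param trace an [accel_trace()].
#' @param start,end half-open 0-based sample range `[start, end)`; the
#'   whole trace when omitted.
#' @param params an [odba_params()].
#' @return Scalar mean per-sample ODBA over the window, in g.
#' @export
odba <- function(trace, start = 0L, end = n_samples(trace),
                 params = odba_params()) {
  s <- odba_series(trace, params)
  mean(s[(start + 1L):end])
}

#' Names of the 28 per-segment summary statistics, in canonical order
#'
#' Eight statistics per axis (mean, min, max, standard deviation, skewness,
#' kurtosis, trend, dominant frequency), three pairwise correlations, and
#' ODBA.
#'
#' @return Character vector of length 28.
#' @export
feature_names <- function() {
  per_axis <- c("mean", "min", "max", "sd", "skew", "kurt", "trend",
                "domfreq")
  c(as.vector(t(outer(c("x", "y", "z"), per_axis,
                      function(a, s) paste0(s, "_", a)))),
    "corr_xy", "corr_xz", "corr_yz", "odba")
}

# population moment ratios; kurtosis is NOT excess (normal -> 3)
moment_skew <- function(v) {
  m <- mean(v); d <- v - m
  m2 <- mean(d^2)
  if (m2 <= 0) return(NA_real_)
  mean(d^3) / m2^1.5
}
moment_kurt <- function(v) {
  m <- mean(v); d <- v - m
  m2 <- mean(d^2)
  if (m2 <= 0) return(NA_real_)
  mean(d^4) / m2^2
}

# OLS slope of value against time in seconds (g per second)
ols_trend <- function(v, tsec) {
  td <- tsec - mean(tsec)
  den <- sum(td^2)
  if (den <= 0) return(NA_real_)
  sum(td * (v - mean(v))) / den
}

# dominant periodogram frequency (Hz): linear detrend, DC excluded
dominant_frequency <- function(v, tsec, rate_hz) {
  n <- length(v)
  if (n < 4L) return(NA_real_)
  res <- v - mean(v) - ols_trend(v, tsec) * (tsec - mean(tsec))
  if (all(abs(res) < 1e-14)) return(0)
  p <- Mod(stats::fft(res))^2
  j <- seq_len(floor(n / 2))           # bins 1 .. n/2, DC excluded
  j[which.max(p[j + 1L])] * rate_hz / n
}

#' Summary statistics for one segment
#'
#' Computes the 28 statistics used as classifier inputs: per axis the
#' mean, min, max, standard deviation (n-1 denominator), skewness and
#' kurtosis as population moment ratios (kurtosis non-excess, so a normal
#' limit gives 3), the ordinary-least-squares trend in g/s, and the
#' dominant periodogram frequency in Hz (linear detrend, zero-frequency
#' term excluded); plus the three pairwise Pearson correlations and ODBA.
#' Skewness and kurtosis need at least 3 samples and are `NA` below that.
#' ODBA uses the static component estimated from the full trace, because
#' typical change-point segments (~0.35 s) are shorter than the 1 s
#' running-mean window.
#'
#' @param trace an [accel_trace()].
#' @param start,end half-open 0-based sample range `[start, end)`, at
#'   least 2 samples.
#' @param params an [odba_params()].
#' @param odba_trace optional pre-computed [odba_series()] for the full
#'   trace, to avoid recomputation across segments.
#' @return Named numeric vector: the 28 statistics of [feature_names()]
#'   plus `n_samples`.
#' @export
segment_features <- function(trace, start, end, params = odba_params(),
                             odba_trace = NULL) {
  stopifnot(inherits(trace, "accel_trace"))
  n <- n_samples(trace)
  if (start < 0L || end > n || end - start < 2L)
    stop("segment [", start, ", ", end, ") out of bounds or too short")
  idx <- (start + 1L):end
  tsec <- trace$time[idx]
  rate <- trace$nominal_rate_hz
  if (is.null(odba_trace)) odba_trace <- odba_series(trace, params)
  ax <- list(x = trace$x[idx], y = trace$y[idx], z = trace$z[idx])
  out <- numeric(0)
  for (a in names(ax)) {
    v <- ax[[a]]
    out <- c(out, setNames(
      c(mean(v), min(v), max(v), stats::sd(v), moment_skew(v),
        moment_kurt(v), ols_trend(v, tsec),
        dominant_frequency(v, tsec, rate)),
      paste0(c("mean", "min", "max", "sd", "skew", "kurt", "trend",
               "domfreq"), "_", a)))
  }
  safe_cor <- function(u, v) {
    if (stats::sd(u) == 0 || stats::sd(v) == 0) return(NA_real_)
    stats::cor(u, v)
  }
  c(out,
    corr_xy = safe_cor(ax$x, ax$y),
    corr_xz = safe_cor(ax$x, ax$z),
    corr_yz = safe_cor(ax$y, ax$z),
    odba = mean(odba_trace[idx]),
    n_samples = length(idx))
}

#' Feature matrix for all segments of a trace
#'
#' @param trace an [accel_trace()].
#' @param segments a [segment_set()] on the same trace.
#' @param params an [odba_params()].
#' @return Data frame with `segment_id`, `start`, `end`, `n_samples` and
#'   the 28 statistics in [feature_names()] order.
#' @export
segment_feature_matrix <- function(trace, segments, params = odba_params()) {
  stopifnot(inherits(segments, "segment_set"))
  os <- odba_series(trace, params)
  segs <- segments$segments
  feats <- t(vapply(seq_len(nrow(segs)), function(i)
    segment_features(trace, segs$start[i], segs$end[i], params,
                     odba_trace = os),
    numeric(29L)))
  out <- data.frame(segment_id = segs$segment_id, start = segs$start,
                    end = segs$end, n_samples = feats[, "n_samples"],
                    feats[, feature_names(), drop = FALSE])
  rownames(out) <- NULL
  out
}
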