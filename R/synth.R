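#' Behaviour schedule for the synthetic generator
#'
#' An ordered list of (behaviour, duration) bouts plus a sampling rate.
#' Labels may come from either ethogram; the plain `flapping` / `soaring`
#' labels behave as their `_straight` variants.
#'
#' @param labels character vector of behaviour labels.
#' @param durations_s bout durations in seconds, all positive.
#' @param sampling_rate_hz sampling rate of the emitted trace.
#' @return An object of class `behavior_schedule`.
#' @export
behavior_schedule <- function(labels, durations_s, sampling_rate_hz = 140) {
  labels <- as.character(labels)
  if (length(labels) == 0L) stop("empty schedule")
  if (length(durations_s) != length(labels))
    stop("labels and durations_s must have equal length")
  if (any(durations_s <= 0)) stop("durations must be > 0")
  known <- c(ethogram("simple")$labels, ethogram("complex")$labels)
  if (!all(labels %in% known))
    stop("unknown behaviour label(s): ",
         paste(setdiff(labels, known), collapse = ", "))
  if (sampling_rate_hz <= 0) stop("sampling_rate_hz must be > 0")
  structure(list(labels = labels, durations_s = as.numeric(durations_s),
                 sampling_rate_hz = sampling_rate_hz),
            class = "behavior_schedule")
}

#' Signal-model parameters for the synthetic generator
#'
#' The generator emits the statistical structure the classification
#' pipeline assumes, per behaviour:
#' * sitting: static gravity `(0, 0, g)` plus white Gaussian noise;
#' * flapping: a sinusoid at the wingbeat frequency on the heave (z) axis
#'   with a smaller in-phase sway (x) component, superposed on gravity;
#' * soaring: low-amplitude first-order autoregressive noise around
#'   gravity (smooth low-frequency drift, unlike white sitting noise);
#' * banking variants: the static gravity vector rolled by
#'   `bank_roll_deg`, giving the constant vector
#'   `(0, -sin(roll), cos(roll)) * g`; the dynamic component is unchanged.
#'
#' White sensor noise is added to every channel on top of the behaviour
#' model.  Defaults are chosen to be realistic for a large raptor: a
#' ~3.5 Hz wingbeat, flap amplitude under 1 g, banking roll above the
#' 20 degree threshold that separates banking from straight flight.
#'
#' @param gravity_g static gravity magnitude (g).
#' @param wingbeat_hz flapping oscillation frequency; must stay below the
#'   Nyquist frequency of the schedule it is used with.
#' @param flap_amplitude_g heave amplitude of the wingbeat sinusoid (g).
#' @param flap_x_ratio in-phase sway amplitude as a fraction of
#'   `flap_amplitude_g`.
#' @param soar_noise_sd_g stationary standard deviation of the soaring
#'   AR(1) process (g).
#' @param soar_ar_coef AR(1) coefficient of the soaring drift.
#' @param sit_noise_sd_g white-noise SD while sitting (g).
#' @param bank_roll_deg roll angle of banking variants, in `[0, 90)`;
#'   banking is defined as a roll of at least ~20 degrees.
#' @param sensor_noise_sd_g white sensor noise SD on every channel (g).
#' @param seed integer seed; identical seed gives an identical trace.
#' @return An object of class `behavior_model_params`.
#' @export
behavior_params <- function(gravity_g = 1.0, wingbeat_hz = 3.5,
                            flap_amplitude_g = 0.8, flap_x_ratio = 0.3,
                            soar_noise_sd_g = 0.05, soar_ar_coef = 0.95,
                            sit_noise_sd_g = 0.01, bank_roll_deg = 25,
                            sensor_noise_sd_g = 0.02, seed = 1) {
  amp <- c(flap_amplitude_g, soar_noise_sd_g, sit_noise_sd_g,
           sensor_noise_sd_g, flap_x_ratio)
  if (any(amp < 0)) stop("amplitudes and noise SDs must be >= 0")
  if (bank_roll_deg < 0 || bank_roll_deg >= 90)
    stop("bank_roll_deg must lie in [0, 90)")
  if (soar_ar_coef < 0 || soar_ar_coef >= 1)
    stop("soar_ar_coef must lie in [0, 1)")
  if (wingbeat_hz <= 0) stop("wingbeat_hz must be > 0")
  structure(list(gravity_g = gravity_g, wingbeat_hz = wingbeat_hz,
                 flap_amplitude_g = flap_amplitude_g,
                 flap_x_ratio = flap_x_ratio,
                 soar_noise_sd_g = soar_noise_sd_g,
                 soar_ar_coef = soar_ar_coef,
                 sit_noise_sd_g = sit_noise_sd_g,
                 bank_roll_deg = bank_roll_deg,
                 sensor_noise_sd_g = sensor_noise_sd_g,
                 seed = as.integer(seed)),
            class = "behavior_model_params")
}

# stationary AR(1) sample of length n with given stationary sd
ar1_noise <- function(n, sd_stat, phi) {
  if (sd_stat == 0 || n == 0L) return(numeric(n))
  innov_sd <- sd_stat * sqrt(1 - phi^2)
  x0 <- stats::rnorm(1, 0, sd_stat)
  as.numeric(stats::filter(stats::rnorm(n, 0, innov_sd), phi,
                           method = "recursive", init = x0))
}

#' Generate a labelled synthetic acceleration trace
#'
#' Emits `floor(total_duration * rate)` samples at the schedule's rate,
#' following the per-behaviour signal models of [behavior_params()], and
#' an annotation track exactly reproducing the schedule boundaries
#' (half-open intervals, no gaps or overlaps).
#'
#' @param schedule a [behavior_schedule()].
#' @param params a [behavior_model_params][behavior_params()].
#' @return List with `trace` (an [accel_trace()]) and `annotations` (an
#'   [annotation_track()]).
#' @export
generate_trace <- function(schedule, params = behavior_params()) {
  stopifnot(inherits(schedule, "behavior_schedule"),
            inherits(params, "behavior_model_params"))
  rate <- schedule$sampling_rate_hz
  if (params$wingbeat_hz >= rate / 2)
    stop("wingbeat_hz is at or above the Nyquist frequency")
  set.seed(params$seed)
  total <- sum(schedule$durations_s)
  n <- floor(total * rate)
  if (n < 2L) stop("schedule too short for the sampling rate")
  tt <- (seq_len(n) - 1L) / rate
  starts <- cumsum(c(0, schedule$durations_s))
  bout <- findInterval(tt, starts, rightmost.closed = FALSE)
  bout[bout > length(schedule$labels)] <- length(schedule$labels)
  x <- numeric(n); y <- numeric(n); z <- numeric(n)
  g <- params$gravity_g
  roll <- params$bank_roll_deg * pi / 180
  for (b in seq_along(schedule$labels)) {
    idx <- which(bout == b)
    if (!length(idx)) next
    lab <- schedule$labels[b]
    banking <- grepl("_banking$", lab)
    static <- if (banking) c(0, -sin(roll) * g, cos(roll) * g) else
      c(0, 0, g)
    x[idx] <- static[1]; y[idx] <- static[2]; z[idx] <- static[3]
    if (grepl("^flapping", lab)) {
      tau <- tt[idx] - starts[b]
      osc <- sin(2 * pi * params$wingbeat_hz * tau)
      z[idx] <- z[idx] + params$flap_amplitude_g * osc
      x[idx] <- x[idx] + params$flap_x_ratio * params$flap_amplitude_g * osc
    } else if (grepl("^soaring", lab)) {
      m <- length(idx)
      x[idx] <- x[idx] + ar1_noise(m, params$soar_noise_sd_g,
                                   params$soar_ar_coef)
      y[idx] <- y[idx] + ar1_noise(m, params$soar_noise_sd_g,
                                   params$soar_ar_coef)
      z[idx] <- z[idx] + ar1_noise(m, params$soar_noise_sd_g,
                                   params$soar_ar_coef)
    } else {                               # sitting
      m <- length(idx)
      x[idx] <- x[idx] + stats::rnorm(m, 0, params$sit_noise_sd_g)
      y[idx] <- y[idx] + stats::rnorm(m, 0, params$sit_noise_sd_g)
      z[idx] <- z[idx] + stats::rnorm(m, 0, params$sit_noise_sd_g)
    }
  }
  if (params$sensor_noise_sd_g > 0) {
    x <- x + stats::rnorm(n, 0, params$sensor_noise_sd_g)
    y <- y + stats::rnorm(n, 0, params$sensor_noise_sd_g)
    z <- z + stats::rnorm(n, 0, params$sensor_noise_sd_g)
  }
  list(trace = accel_trace(tt, x, y, z, nominal_rate_hz = rate),
       annotations = annotation_track(starts[-length(starts)],
                                      starts[-1L], schedule$labels))
}

#' Generate a benchmark set of labelled traces
#'
#' Draws, per trace, a behaviour sequence (no immediate repeats) with a
#' class mix that puts soaring first, flapping second and sitting last —
#' matching the prevalence ordering typical of a soaring raptor — and
#' bout durations from a log-normal distribution with mean
#' `mean_duration_s` (default 0.35 s, the scale of change-point segments
#' observed at 140 Hz).  Everything is reproducible from `seed`.
#'
#' @param n_traces number of traces (>= 1).
#' @param eth target [ethogram()]; `"complex"` traces include banking
#'   variants (and can always be relabelled simple downstream).
#' @param seed integer seed.
#' @param mean_duration_s mean bout duration (s).
#' @param duration_sdlog log-scale SD of the bout-duration log-normal.
#' @param trace_duration_s approximate duration of each trace (s); bouts
#'   are appended until this is reached.
#' @param rate_hz sampling rate.
#' @param params a [behavior_params()] signal model (its seed is
#'   re-drawn per trace from the master seed).
#' @return List of `n_traces` elements, each with `trace`, `annotations`
#'   and `schedule`.
#' @export
generate_benchmark <- function(n_traces = 5, eth = ethogram("complex"),
                               seed = 1, mean_duration_s = 0.35,
                               duration_sdlog = 0.6,
                               trace_duration_s = 40, rate_hz = 140,
                               params = behavior_params()) {
  stopifnot(n_traces >= 1, inherits(eth, "ethogram"))
  weights <- if (eth$name == "simple")
    c(flapping = 0.28, soaring = 0.58, sitting = 0.14)
  else
    c(flapping_straight = 0.114, flapping_banking = 0.168,
      soaring_straight = 0.384, soaring_banking = 0.195, sitting = 0.139)
  weights <- weights / sum(weights)
  meanlog <- log(mean_duration_s) - duration_sdlog^2 / 2
  set.seed(seed)
  out <- vector("list", n_traces)
  for (i in seq_len(n_traces)) {
    labs <- character(0); durs <- numeric(0); tot <- 0
    prev <- NA_character_
    while (tot < trace_duration_s) {
      w <- weights
      if (!is.na(prev)) w[prev] <- 0            # no immediate repeats
      lab <- sample(names(w), 1, prob = w / sum(w))
      d <- stats::rlnorm(1, meanlog, duration_sdlog)
      labs <- c(labs, lab); durs <- c(durs, d)
      tot <- tot + d
      prev <- lab
    }
    p <- params
    p$seed <- sample.int(2^30, 1)
    sched <- behavior_schedule(labs, durs, rate_hz)
    gen <- generate_trace(sched, p)
    out[[i]] <- list(trace = gen$trace, annotations = gen$annotations,
                     schedule = sched)
  }
  out
}
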