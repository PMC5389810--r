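# Shared fixtures.  Heavy objects are built lazily and memoised so the
# cost is paid once per test run regardless of which files use them.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- builder()
  .fixtures[[key]]
}

# thresholds for the scaled-down monitor used throughout the tests
test_thresholds <- function() {
  memo("th500", function() {
    calibrate_thresholds(cpm_params(arl0 = 500, startup = 100,
                                    calibration_reps = 1000, seed = 7),
                         horizon = 3000)
  })
}

# a noiseless pure-sine trace (z axis), handy for feature oracles
sine_trace <- function(freq_hz = 4, dur_s = 2, rate = 140) {
  tt <- (0:(dur_s * rate - 1)) / rate
  accel_trace(tt, rep(0, length(tt)), rep(0, length(tt)),
              sin(2 * pi * freq_hz * tt), nominal_rate_hz = rate)
}

# small labelled benchmark shared by classifier tests (not the full
# acceptance-scale benchmark)
small_benchmark <- function() {
  memo("bm_small", function() {
    generate_benchmark(n_traces = 2, seed = 11, trace_duration_s = 25)
  })
}

# acceptance-scale benchmark: the generator's default study conditions
acceptance_benchmark <- function() {
  memo("bm_acc", function() {
    generate_benchmark(n_traces = 5, seed = 2026, trace_duration_s = 40)
  })
}

# full pipeline on the acceptance benchmark at the working ARL0 = 50,000
# (shipped threshold curve): segments with simple + complex labels, and
# per-sample tables for the KNN
acceptance_pipeline <- function() {
  memo("pipe_acc", function() {
    bm <- acceptance_benchmark()
    cfg <- study_config()
    segs <- NULL
    samp_s <- NULL
    samp_c <- NULL
    for (b in bm) {
      tr <- b$trace
      p <- cfg$cpm
      p$startup <- max(round(tr$nominal_rate_hz), 2 * p$min_side)
      ss <- segment_stream(tr, p)
      lab_s <- assign_labels(ss, b$annotations, tr, ethogram("simple"))
      lab_c <- assign_labels(ss, b$annotations, tr, ethogram("complex"))
      fm <- segment_feature_matrix(tr, ss)
      fm$label <- lab_s$label
      fm$label_complex <- lab_c$label
      fm <- fm[lab_s$kept & lab_c$kept &
                 stats::complete.cases(fm[, feature_names()]), ]
      segs <- rbind(segs, fm)
      sl_s <- sample_labels(tr, b$annotations, ethogram("simple"))
      sl_c <- sample_labels(tr, b$annotations, ethogram("complex"))
      keep <- !is.na(sl_s)
      samp_s <- rbind(samp_s, data.frame(x = tr$x[keep], y = tr$y[keep],
                                         z = tr$z[keep],
                                         label = sl_s[keep]))
      samp_c <- rbind(samp_c, data.frame(x = tr$x[keep], y = tr$y[keep],
                                         z = tr$z[keep],
                                         label = sl_c[keep]))
    }
    list(segments = segs, samples_simple = samp_s, samples_complex = samp_c)
  })
}

# segment + feature + label the small benchmark with the scaled monitor
small_pipeline <- function() {
  memo("pipe_small", function() {
    bm <- small_benchmark()
    th <- test_thresholds()
    p <- cpm_params(arl0 = 500, calibration_reps = 1000, seed = 7)
    segs <- NULL
    for (b in bm) {
      tr <- b$trace
      pp <- p
      pp$startup <- round(tr$nominal_rate_hz)
      ss <- segment_stream(tr, pp, thresholds = th)
      lab_s <- assign_labels(ss, b$annotations, tr, ethogram("simple"))
      lab_c <- assign_labels(ss, b$annotations, tr, ethogram("complex"))
      fm <- segment_feature_matrix(tr, ss)
      fm$label <- lab_s$label
      fm$label_complex <- lab_c$label
      fm <- fm[lab_s$kept & stats::complete.cases(fm[, feature_names()]), ]
      segs <- rbind(segs, fm)
    }
    segs
  })
}
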