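#' Subsample a trace to a lower rate by grid-nearest decimation
#'
#' For each instant of the target time grid the nearest original sample is
#' kept (earlier sample on exact ties), each original sample at most once.
#' No anti-alias filter is applied: this reproduces plain subsampling of a
#' logged stream, so signal content above the new Nyquist frequency
#' aliases.  140 -> 20 Hz keeps every 7th sample exactly; a non-integer
#' factor such as 140 -> 40 Hz alternates steps of 3 and 4.
#'
#' @param trace an [accel_trace()].
#' @param target_hz target rate; a target at or above the native rate
#'   returns the trace unchanged with a warning.
#' @return A decimated [accel_trace()].
#' @export
subsample_trace <- function(trace, target_hz) {
  stopifnot(inherits(trace, "accel_trace"))
  if (target_hz <= 0) stop("target_hz must be > 0")
  if (target_hz >= trace$nominal_rate_hz) {
    warning("target rate not below the native rate; returning unchanged")
    return(trace)
  }
  tg <- seq(trace$time[1], trace$time[n_samples(trace)], by = 1 / target_hz)
  lo <- findInterval(tg, trace$time)
  hi <- pmin(lo + 1L, n_samples(trace))
  pick_hi <- (trace$time[hi] - tg) < (tg - trace$time[lo])  # ties -> earlier
  idx <- unique(ifelse(pick_hi, hi, lo))
  accel_trace(trace$time[idx], trace$x[idx], trace$y[idx], trace$z[idx])
}

#' Configuration for the end-to-end pipeline runs
#'
#' Bundles the pieces the frequency study and the behaviour budget need:
#' the change-point settings (startup is re-derived per rate as one second
#' of data), the ODBA window, the target ethogram, and fixed classifier
#' hyper-parameters (grid-searching every subsampled rate would multiply
#' runtime for no extra insight; `ntree = 1500`, `mtry = 7` are the
#' optimum this pipeline typically selects, and K is re-optimized per rate
#' by the standard coarse-then-unit search unless fixed here).
#'
#' @param cpm a [cpm_params()].
#' @param odba an [odba_params()].
#' @param eth an [ethogram()].
#' @param rf_ntree,rf_mtry fixed random-forest hyper-parameters.
#' @param knn a [knn_config()], or a single integer to fix K.
#' @param wingbeat_hz expected wingbeat frequency, used only to flag rates
#'   whose Nyquist frequency falls below it.
#' @return An object of class `study_config`.
#' @export
study_config <- function(cpm = cpm_params(), odba = odba_params(),
                         eth = ethogram("simple"), rf_ntree = 1500,
                         rf_mtry = 7, knn = knn_config(),
                         wingbeat_hz = 3.5) {
  structure(list(cpm = cpm, odba = odba, eth = eth, rf_ntree = rf_ntree,
                 rf_mtry = rf_mtry, knn = knn, wingbeat_hz = wingbeat_hz),
            class = "study_config")
}

# run segmentation + features + labels over a benchmark at one rate;
# returns pooled kept segments with labels, and pooled per-sample data
pipeline_at_rate <- function(benchmark, rate, config, native = FALSE) {
  feats <- list(); samp <- list()
  for (i in seq_along(benchmark)) {
    tr <- benchmark[[i]]$trace
    if (!native) tr <- subsample_trace(tr, rate)
    p <- config$cpm
    p$startup <- max(round(tr$nominal_rate_hz), 2 * p$min_side)
    segs <- segment_stream(tr, p)
    lab <- assign_labels(segs, benchmark[[i]]$annotations, tr, config$eth)
    fm <- segment_feature_matrix(tr, segs, config$odba)
    fm$label <- lab$label
    fm <- fm[lab$kept & stats::complete.cases(fm[, feature_names()]), ,
             drop = FALSE]
    feats[[i]] <- fm
    sl <- sample_labels(tr, benchmark[[i]]$annotations, config$eth)
    keep <- !is.na(sl)
    samp[[i]] <- data.frame(x = tr$x[keep], y = tr$y[keep],
                            z = tr$z[keep], label = sl[keep],
                            stringsAsFactors = FALSE)
  }
  list(segments = do.call(rbind, feats), samples = do.call(rbind, samp))
}

#' Sampling-frequency study
#'
#' Runs the full segment -> featurize -> label -> train -> evaluate
#' pipeline on the benchmark subsampled to each target rate (plus the
#' native rate), for both classifiers, and locates the inflection rate:
#' the lowest rate whose accuracy is within `eps` of the best accuracy
#' over all rates.  The RF is evaluated per segment, the KNN per sample,
#' each on its own stratified 70/30 split.
#'
#' @param benchmark a [generate_benchmark()] result (generated at the
#'   native rate).
#' @param rates target rates in Hz below the native rate.
#' @param config a [study_config()].
#' @param seed integer seed for the splits.
#' @param eps inflection tolerance on absolute accuracy.
#' @return An object of class `frequency_study`: `results` data frame
#'   (one row per rate) plus `inflection_rf` and `inflection_knn`.
#' @export
frequency_study <- function(benchmark, rates = c(5, 10, 20, 40),
                            config = study_config(), seed = 1,
                            eps = 0.01) {
  native_rate <- benchmark[[1]]$trace$nominal_rate_hz
  if (any(rates >= native_rate)) stop("rates must be below the native rate")
  rates <- sort(rates)
  all_rates <- c(rates, native_rate)
  rows <- vector("list", length(all_rates))
  for (r in seq_along(all_rates)) {
    rate <- all_rates[r]
    native <- r == length(all_rates)
    dat <- pipeline_at_rate(benchmark, rate, config, native = native)
    # RF, per segment; very low rates can yield too few segments (or a
    # single class) to train on — those rates are reported as NA
    seg_counts <- table(dat$segments$label)
    if (length(seg_counts) >= 2 && all(seg_counts >= 2) &&
        nrow(dat$segments) >= 10) {
      sp <- split_70_30(dat$segments$label, seed = seed + r)
      rf <- behavior_rf(dat$segments[sp$train, feature_names()],
                        dat$segments$label[sp$train],
                        ntree = config$rf_ntree, mtry = config$rf_mtry,
                        seed = seed + r)
      rf_pred <- predict(rf, dat$segments[sp$test, feature_names()])
      rf_acc <- mean(rf_pred == dat$segments$label[sp$test])
    } else {
      warning(sprintf(
        "rate %g Hz: too few labelled segments to train on; flagged", rate))
      rf_acc <- NA_real_
    }
    # KNN, per sample
    sps <- split_70_30(dat$samples$label, seed = seed + 100 + r)
    xyz <- c("x", "y", "z")
    if (inherits(config$knn, "knn_config")) {
      kr <- knn_optimize(dat$samples[sps$train, xyz],
                         dat$samples$label[sps$train],
                         dat$samples[sps$test, xyz],
                         dat$samples$label[sps$test], config$knn)
      knn_acc <- kr$accuracy; knn_k <- kr$k
    } else {
      model <- behavior_knn(dat$samples[sps$train, xyz],
                            dat$samples$label[sps$train],
                            k = config$knn)
      pred <- predict(model, dat$samples[sps$test, xyz])
      knn_acc <- mean(pred == dat$samples$label[sps$test])
      knn_k <- config$knn
    }
    rows[[r]] <- data.frame(
      rate_hz = rate, native = native, rf_accuracy = rf_acc,
      knn_accuracy = knn_acc, knn_k = knn_k,
      n_segments = nrow(dat$segments), n_samples = nrow(dat$samples),
      aliased = rate < 2 * config$wingbeat_hz)
  }
  res <- do.call(rbind, rows)
  inflect <- function(acc) {
    ok <- !is.na(acc)
    res$rate_hz[ok][acc[ok] >= max(acc[ok]) - eps][1]
  }
  structure(list(results = res, eps = eps,
                 inflection_rf = inflect(res$rf_accuracy),
                 inflection_knn = inflect(res$knn_accuracy)),
            class = "frequency_study")
}

#' @export
print.frequency_study <- function(x, ...) {
  cat("<frequency_study>\n")
  df <- x$results
  df$rf_accuracy <- round(df$rf_accuracy, 4)
  df$knn_accuracy <- round(df$knn_accuracy, 4)
  print(df, row.names = FALSE)
  cat(sprintf("inflection (eps = %.2g): RF %.6g Hz, KNN %.6g Hz\n",
              x$eps, x$inflection_rf, x$inflection_knn))
  invisible(x)
}

#' @export
plot.frequency_study <- function(x, ...) {
  res <- x$results
  graphics::plot(res$rate_hz, res$rf_accuracy, type = "b", pch = 19,
                 ylim = range(c(res$rf_accuracy, res$knn_accuracy)),
                 xlab = "sampling rate (Hz)", ylab = "overall accuracy",
                 ...)
  graphics::lines(res$rate_hz, res$knn_accuracy, type = "b", pch = 17,
                  lty = 2)
  graphics::legend("bottomright", c("RF (per segment)", "KNN (per sample)"),
                   pch = c(19, 17), lty = c(1, 2), bty = "n")
  invisible(x)
}

#' Behaviour time budget of an unlabelled trace
#'
#' Classifies a stream with a trained model and aggregates classified
#' duration per behaviour (fractions normalized over classified time),
#' optionally broken down by hour of day.  A segment model
#' ([behavior_rf()]) classifies change-point segments; a sample model
#' ([behavior_knn()]) classifies every measurement.
#'
#' @param trace an [accel_trace()].
#' @param model a [behavior_rf()] or [behavior_knn()].
#' @param config a [study_config()] (segmentation and ODBA settings for
#'   the RF path).
#' @param clock_start_s optional clock time (seconds since local
#'   midnight) of the first sample, enabling the per-hour breakdown.
#' @return An object of class `behavior_budget`: `fractions` (named,
#'   summing to 1 over the model's classes), `hourly` (data frame or
#'   `NULL`), `classified_time_s`.
#' @export
behavior_budget <- function(trace, model, config = study_config(),
                            clock_start_s = NULL) {
  stopifnot(inherits(trace, "accel_trace"))
  if (inherits(model, "behavior_rf")) {
    p <- config$cpm
    p$startup <- max(round(trace$nominal_rate_hz), 2 * p$min_side)
    segs <- segment_stream(trace, p)
    fm <- segment_feature_matrix(trace, segs, config$odba)
    ok <- stats::complete.cases(fm[, feature_names()])
    pred <- predict(model, fm[ok, feature_names()])
    dur <- (fm$end[ok] - fm$start[ok]) / trace$nominal_rate_hz
    mid <- (fm$start[ok] + fm$end[ok]) / 2 / trace$nominal_rate_hz
  } else if (inherits(model, "behavior_knn")) {
    pred <- predict(model, cbind(x = trace$x, y = trace$y, z = trace$z))
    dur <- rep(1 / trace$nominal_rate_hz, n_samples(trace))
    mid <- trace$time
  } else stop("model must be a behavior_rf or behavior_knn")
  if (!length(pred)) stop("nothing classified")
  classes <- model$classes
  total <- sum(dur)
  fr <- vapply(classes, function(cl) sum(dur[pred == cl]) / total, 0)
  hourly <- NULL
  if (!is.null(clock_start_s)) {
    hr <- floor(((clock_start_s + mid) %% 86400) / 3600)
    hourly <- do.call(rbind, lapply(sort(unique(hr)), function(h) {
      sel <- hr == h
      data.frame(hour = h, label = classes,
                 fraction = vapply(classes, function(cl)
                   sum(dur[sel & pred == cl]) / sum(dur[sel]), 0),
                 row.names = NULL)
    }))
  }
  structure(list(fractions = fr, hourly = hourly,
                 classified_time_s = total,
                 model_class = class(model)[1]),
            class = "behavior_budget")
}

#' @export
print.behavior_budget <- function(x, ...) {
  cat(sprintf("<behavior_budget> %.1f s classified (%s)\n",
              x$classified_time_s, x$model_class))
  for (cl in names(x$fractions))
    cat(sprintf("  %-18s %6.2f%%\n", cl, 100 * x$fractions[cl]))
  invisible(x)
}
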