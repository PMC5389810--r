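#' Behaviour ethograms
#'
#' Two behaviour catalogues are supported: a simple 3-class scheme
#' (flapping, soaring, sitting) and a complex 5-class scheme separating
#' straight from banking flight, where banking means the body rolled by
#' roughly 20 degrees or more.  Every complex label maps onto a simple one.
#'
#' @param name `"simple"` or `"complex"`.
#' @return An object of class `ethogram` with fields `name`, `labels` and
#'   `to_simple` (a named character map, identity for the simple scheme).
#' @export
ethogram <- function(name = c("simple", "complex")) {
  name <- match.arg(name)
  if (name == "simple") {
    labels <- c("flapping", "soaring", "sitting")
    to_simple <- setNames(labels, labels)
  } else {
    labels <- c("flapping_straight", "flapping_banking", "soaring_straight",
                "soaring_banking", "sitting")
    to_simple <- c(flapping_straight = "flapping",
                   flapping_banking = "flapping",
                   soaring_straight = "soaring",
                   soaring_banking = "soaring",
                   sitting = "sitting")
  }
  structure(list(name = name, labels = labels, to_simple = to_simple),
            class = "ethogram")
}

#' @export
print.ethogram <- function(x, ...) {
  cat(sprintf("<ethogram> %s: %s\n", x$name,
              paste(x$labels, collapse = ", ")))
  invisible(x)
}

#' Collapse complex labels to the simple ethogram
#'
#' `flapping_*` becomes `flapping`, `soaring_*` becomes `soaring`,
#' `sitting` stays `sitting`.
#'
#' @param labels character vector of complex (or already simple) labels.
#' @param eth the [ethogram()] defining the mapping; default complex.
#' @return Character vector of simple labels.
#' @export
map_to_simple <- function(labels, eth = ethogram("complex")) {
  stopifnot(inherits(eth, "ethogram"))
  labels <- as.character(labels)
  unknown <- setdiff(unique(labels), names(eth$to_simple))
  if (length(unknown))
    stop("unknown label(s): ", paste(unknown, collapse = ", "))
  unname(eth$to_simple[labels])
}

#' Assign annotated behaviours to change-point segments
#'
#' Each segment's overlap duration with every annotation label is computed
#' by half-open interval intersection on the time axis, and the segment
#' takes the label occupying the majority of its annotated time.  Segments
#' overlapping an excluded interval by any amount are dropped
#' (`drop_reason = "excluded"`); segments with no annotation cover are
#' dropped (`drop_reason = "unannotated"`).  A tie in majority duration is
#' broken in favour of the behaviour whose overlapping interval starts
#' earliest, and flagged.
#'
#' @param segments a [segment_set()].
#' @param annotations an [annotation_track()] whose labels (ignoring
#'   excluded intervals) belong to `eth`.
#' @param trace the segmented [accel_trace()] (provides the time axis).
#' @param eth the target [ethogram()]; complex annotation labels are
#'   collapsed automatically when `eth` is simple.
#' @return An object of class `labeled_segments`: a data frame with
#'   `segment_id`, `start`, `end`, `label`, `majority_fraction`, `kept`,
#'   `drop_reason` and `tie`.
#' @export
assign_labels <- function(segments, annotations, trace,
                          eth = ethogram("simple")) {
  stopifnot(inherits(segments, "segment_set"),
            inherits(annotations, "annotation_track"),
            inherits(trace, "accel_trace"), inherits(eth, "ethogram"))
  n <- n_samples(trace)
  # segment [start, end) in time: sample i covers [time_i, time_{i+1})
  step <- 1 / trace$nominal_rate_hz
  tgrid <- c(trace$time, trace$time[n] + step)
  ann <- as.data.frame(annotations)
  ann$use_label <- ann$label
  if (eth$name == "simple") {
    conv <- ann$label %in% names(ethogram("complex")$to_simple)
    ann$use_label[conv] <- map_to_simple(ann$label[conv])
  }
  bad <- !ann$excluded & !(ann$use_label %in% eth$labels)
  if (any(bad))
    stop("annotation label(s) outside the ethogram: ",
         paste(unique(ann$use_label[bad]), collapse = ", "))
  segs <- segments$segments
  m <- nrow(segs)
  label <- character(m); frac <- rep(NA_real_, m)
  kept <- logical(m); reason <- rep(NA_character_, m); tie <- logical(m)
  for (i in seq_len(m)) {
    s0 <- tgrid[segs$start[i] + 1L]
    s1 <- tgrid[segs$end[i] + 1L]
    ov <- pmin(ann$end_s, s1) - pmax(ann$start_s, s0)
    hit <- ov > 0
    if (any(hit & ann$excluded)) {
      reason[i] <- "excluded"
      next
    }
    if (!any(hit)) {
      reason[i] <- "unannotated"
      next
    }
    dur <- tapply(ov[hit], ann$use_label[hit], sum)
    first_start <- tapply(ann$start_s[hit], ann$use_label[hit], min)
    best <- max(dur)
    winners <- names(dur)[dur >= best - 1e-12]
    if (length(winners) > 1L) {
      tie[i] <- TRUE
      winners <- winners[order(first_start[winners])]
    }
    label[i] <- winners[1L]
    frac[i] <- best / sum(dur)
    kept[i] <- TRUE
  }
  out <- data.frame(segment_id = segs$segment_id, start = segs$start,
                    end = segs$end, label = ifelse(kept, label, NA),
                    majority_fraction = frac, kept = kept,
                    drop_reason = reason, tie = tie,
                    stringsAsFactors = FALSE)
  class(out) <- c("labeled_segments", "data.frame")
  attr(out, "ethogram") <- eth$name
  out
}

#' Count kept segments per behaviour label
#'
#' @param labeled a [assign_labels()] result.
#' @return Named integer vector of counts over kept segments; the sum
#'   equals the number of kept segments.
#' @export
class_counts <- function(labeled) {
  stopifnot(inherits(labeled, "labeled_segments"))
  tab <- table(labeled$label[labeled$kept])
  setNames(as.integer(tab), names(tab))
}

#' Per-sample behaviour labels from an annotation track
#'
#' Labels each sample by the half-open annotation interval containing its
#' timestamp.  Samples in excluded intervals or outside any interval get
#' `NA`.  This is the labelling unit for the per-sample KNN classifier.
#'
#' @param trace an [accel_trace()].
#' @param annotations an [annotation_track()].
#' @param eth target [ethogram()]; complex labels are collapsed when `eth`
#'   is simple.
#' @return Character vector, one label (or `NA`) per sample.
#' @export
sample_labels <- function(trace, annotations, eth = ethogram("simple")) {
  stopifnot(inherits(trace, "accel_trace"),
            inherits(annotations, "annotation_track"))
  ann <- as.data.frame(annotations)
  lab <- ann$label
  if (eth$name == "simple") {
    conv <- lab %in% names(ethogram("complex")$to_simple)
    lab[conv] <- map_to_simple(lab[conv])
  }
  pos <- findInterval(trace$time, ann$start_s)
  out <- rep(NA_character_, n_samples(trace))
  inside <- pos >= 1L & trace$time < ann$end_s[pmax(pos, 1L)]
  ok <- inside & !ann$excluded[pmax(pos, 1L)]
  out[ok] <- lab[pos[ok]]
  out
}
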