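#' Construct an annotation track
#'
#' Labelled behaviour intervals on the trace's time axis.  Intervals are
#' half-open `[start_s, end_s)` so abutting intervals tile without overlap;
#' a sample belongs to the interval containing its timestamp.  Intervals
#' flagged `excluded` (for example the bird sitting on the trainer's glove,
#' or out of the video frame) are kept for bookkeeping but any segment
#' touching them is dropped from classification.
#'
#' @param start_s,end_s interval bounds in seconds, `start_s < end_s`.
#' @param label behaviour label per interval, non-empty strings.
#' @param excluded logical flag per interval (recycled).
#' @return An object of class `annotation_track` (a data frame).
#' @export
annotation_track <- function(start_s, end_s, label, excluded = FALSE) {
  df <- data.frame(start_s = as.numeric(start_s), end_s = as.numeric(end_s),
                   label = as.character(label),
                   excluded = as.logical(rep_len(excluded, length(start_s))),
                   stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("annotation track must have at least one interval")
  if (any(!nzchar(df$label))) stop("labels must be non-empty")
  if (any(df$end_s <= df$start_s)) stop("intervals must satisfy start < end")
  df <- df[order(df$start_s, df$end_s), , drop = FALSE]
  rownames(df) <- NULL
  if (nrow(df) > 1L && any(df$start_s[-1L] < df$end_s[-nrow(df)]))
    stop("overlapping annotation intervals")
  class(df) <- c("annotation_track", "data.frame")
  df
}

#' Read an annotation track from CSV
#'
#' Expects columns `start_s,end_s,label,excluded`.
#'
#' @param path file path.
#' @return An [annotation_track()].
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("start_s", "end_s", "label", "excluded")
  if (!all(need %in% names(raw)))
    stop("annotation file must have columns ", paste(need, collapse = ", "))
  annotation_track(raw$start_s, raw$end_s, raw$label,
                   as.logical(raw$excluded))
}

#' Write an annotation track as CSV
#' @param annotations an [annotation_track()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  stopifnot(inherits(annotations, "annotation_track"))
  df <- as.data.frame(annotations)
  df$start_s <- format(df$start_s, digits = 15, trim = TRUE,
                       scientific = FALSE)
  df$end_s <- format(df$end_s, digits = 15, trim = TRUE, scientific = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
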