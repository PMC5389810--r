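#' Write / read a segment table
#'
#' One row per segment with its half-open 0-based sample range and, for
#' every segment whose end is a detected boundary, the detection delay in
#' samples.  `read_segments(write_segments(x))` reproduces `x` exactly.
#'
#' @param segments a [segment_set()].
#' @param path output path (CSV).
#' @return `path` invisibly (write); a [segment_set()] (read).
#' @export
write_segments <- function(segments, path) {
  stopifnot(inherits(segments, "segment_set"))
  segs <- segments$segments
  delay <- c(segments$detection_delays, NA_integer_)
  df <- data.frame(segment_id = segs$segment_id, start = segs$start,
                   end = segs$end, detection_delay = delay)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_segments
#' @export
read_segments <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path)
  need <- c("segment_id", "start", "end", "detection_delay")
  if (!all(need %in% names(df)))
    stop("segment file must have columns ", paste(need, collapse = ", "))
  df <- df[order(df$start), , drop = FALSE]
  n <- df$end[nrow(df)]
  segment_set(c(df$start, n), n,
              detection_delays = df$detection_delay[-nrow(df)])
}

#' Write / read a per-segment feature matrix
#'
#' Columns are `segment_id`, `start`, `end`, `n_samples`, an optional
#' `label`, then the 28 statistics in [feature_names()] order; the header
#' is checked on both ends so feature order is part of the contract.
#'
#' @param features a data frame from [segment_feature_matrix()] (with an
#'   optional `label` column added).
#' @param path output path (CSV).
#' @return `path` invisibly (write); the data frame (read).
#' @export
write_features <- function(features, path) {
  meta <- intersect(c("segment_id", "start", "end", "n_samples", "label"),
                    names(features))
  miss <- setdiff(feature_names(), names(features))
  if (length(miss))
    stop("feature matrix is missing: ", paste(miss, collapse = ", "))
  df <- features[, c(meta, feature_names())]
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(v)
    format(v, digits = 15, trim = TRUE, scientific = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path)
  miss <- setdiff(feature_names(), names(df))
  if (length(miss))
    stop("feature file is missing: ", paste(miss, collapse = ", "))
  df
}

#' Serialize a confusion report
#'
#' Writes the report twice: machine-readable structured JSON at `path`,
#' and a human-readable per-class CSV table next to it (`.csv` extension).
#'
#' @param report a [confusion_metrics()] result.
#' @param path output path for the JSON form.
#' @return Named character vector of the two paths, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "confusion_report"))
  payload <- list(
    classes = rownames(report$table),
    confusion = as.data.frame.matrix(report$table),
    per_class = report$per_class,
    overall_accuracy = report$overall_accuracy,
    kappa = report$kappa,
    n = report$n)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  csv_path <- sub("\\.json$", ".csv", path)
  if (identical(csv_path, path)) csv_path <- paste0(path, ".csv")
  utils::write.csv(report$per_class, csv_path, row.names = FALSE)
  invisible(c(json = path, csv = csv_path))
}
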