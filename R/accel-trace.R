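#' Construct an acceleration trace
#'
#' A trace holds timestamped tri-axial acceleration in units of g, with the
#' body-frame convention x = sway (lateral), y = surge (anterior-posterior),
#' z = heave (dorso-ventral); gravity lies along +z when the bird is level.
#'
#' @param time numeric vector of timestamps in seconds, strictly increasing.
#' @param x,y,z acceleration channels in g, same length as `time`.
#' @param nominal_rate_hz mean sampling rate; computed as
#'   `(n - 1) / (time[n] - time[1])` when omitted.
#' @return An object of class `accel_trace`.
#' @export
accel_trace <- function(time, x, y, z, nominal_rate_hz = NULL) {
  time <- as.numeric(time)
  x <- as.numeric(x); y <- as.numeric(y); z <- as.numeric(z)
  n <- length(time)
  if (n < 2L) stop("an accel_trace needs at least 2 samples")
  if (length(x) != n || length(y) != n || length(z) != n)
    stop("time, x, y, z must have equal length")
  if (any(!is.finite(time)) || any(diff(time) <= 0))
    stop("time must be finite and strictly increasing")
  if (is.null(nominal_rate_hz))
    nominal_rate_hz <- (n - 1) / (time[n] - time[1])
  if (!is.finite(nominal_rate_hz) || nominal_rate_hz <= 0)
    stop("nominal_rate_hz must be positive")
  structure(list(time = time, x = x, y = y, z = z,
                 nominal_rate_hz = nominal_rate_hz),
            class = "accel_trace")
}

#' @export
print.accel_trace <- function(x, ...) {
  cat(sprintf("<accel_trace> %d samples, %.3f s, nominal rate %.2f Hz\n",
              length(x$time), x$time[length(x$time)] - x$time[1],
              x$nominal_rate_hz))
  invisible(x)
}

#' Number of samples in a trace
#' @param trace an [accel_trace()].
#' @return integer sample count.
#' @export
n_samples <- function(trace) length(trace$time)

#' Read an acceleration trace from a delimited file
#'
#' Expects a comma-separated file with a header row.  Rows where any mapped
#' column fails to parse as a number are dropped with a warning giving the
#' count.  Rows are sorted by time; ties or non-finite times after the sort
#' are an error.
#'
#' @param path file path.
#' @param column_map named character vector mapping the canonical channel
#'   names `time`, `x`, `y`, `z` to the file's column names.
#' @return An [accel_trace()].
#' @export
read_accel_csv <- function(path,
                           column_map = c(time = "time_s", x = "x_g",
                                          y = "y_g", z = "z_g")) {
  if (!file.exists(path)) stop("file not found: ", path)
  need <- c("time", "x", "y", "z")
  if (!all(need %in% names(column_map)))
    stop("column_map must name time, x, y and z columns")
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  missing_cols <- setdiff(unname(column_map[need]), names(raw))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  cols <- lapply(need, function(ch)
    suppressWarnings(as.numeric(raw[[column_map[[ch]]]])))
  names(cols) <- need
  ok <- Reduce(`&`, lapply(cols, is.finite))
  n_bad <- sum(!ok)
  if (n_bad > 0L)
    warning(sprintf("dropped %d row(s) with unparseable values", n_bad))
  cols <- lapply(cols, `[`, ok)
  if (length(cols$time) < 2L) stop("fewer than 2 valid rows in ", path)
  o <- order(cols$time)
  cols <- lapply(cols, `[`, o)
  if (any(diff(cols$time) <= 0))
    stop("time is non-monotone after sorting (duplicate timestamps)")
  accel_trace(cols$time, cols$x, cols$y, cols$z)
}

#' Write an acceleration trace as CSV
#'
#' Columns `time_s,x_g,y_g,z_g`, full double precision, so that
#' `read_accel_csv()` round-trips losslessly to well below 1e-6 g.
#'
#' @param trace an [accel_trace()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_accel_csv <- function(trace, path) {
  stopifnot(inherits(trace, "accel_trace"))
  df <- data.frame(time_s = trace$time, x_g = trace$x, y_g = trace$y,
                   z_g = trace$z)
  utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
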