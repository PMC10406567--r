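#' Construct an RR-interval series
#'
#' An `rr_series` holds a sequence of interbeat (RR) intervals together with
#' the cumulative beat times, a per-beat artifact flag, and a marker saying
#' whether artifact correction has been applied.  Beat `i` occurs at the
#' cumulative sum of intervals `1..i`, in seconds; the recording starts at
#' `t = 0` before the first interval.
#'
#' @param intervals numeric vector of RR intervals in milliseconds; all must
#'   be positive and below 5000 ms.
#' @param beat_times optional numeric vector of beat occurrence times in
#'   seconds.  When omitted it is derived as `cumsum(intervals) / 1000`.
#' @param flags optional character vector of per-beat artifact classes, one of
#'   `"normal"`, `"ectopic"`, `"missed"`, `"extra"`, `"long_short"`.
#' @param corrected logical; whether artifact correction has been applied.
#' @return an object of class `rr_series` with elements `intervals`,
#'   `beat_times`, `flags` and `corrected`.
#' @seealso [read_rr()], [detect_artifacts()], [correct_artifacts()]
#' @export
rr_series <- function(intervals, beat_times = NULL, flags = NULL,
                      corrected = FALSE) {
  intervals <- as.numeric(intervals)
  if (length(intervals) == 0L)
    stop("rr_series: no intervals supplied")
  bad <- which(!is.finite(intervals) | intervals <= 0 | intervals >= 5000)
  if (length(bad))
    stop(sprintf("rr_series: invalid interval at position %d (value %s)",
                 bad[1L], format(intervals[bad[1L]])))
  if (is.null(beat_times)) {
    beat_times <- cumsum(intervals) / 1000
  } else {
    beat_times <- as.numeric(beat_times)
    if (length(beat_times) != length(intervals))
      stop("rr_series: beat_times and intervals differ in length")
    if (any(diff(beat_times) <= 0))
      stop("rr_series: beat_times must be strictly increasing")
  }
  if (is.null(flags)) {
    flags <- rep("normal", length(intervals))
  } else {
    flags <- as.character(flags)
    if (length(flags) != length(intervals))
      stop("rr_series: flags and intervals differ in length")
    ok <- flags %in% c("normal", "ectopic", "missed", "extra", "long_short")
    if (!all(ok))
      stop("rr_series: unknown artifact flag: ", flags[which(!ok)[1L]])
  }
  structure(list(intervals = intervals, beat_times = beat_times,
                 flags = flags, corrected = isTRUE(corrected)),
            class = "rr_series")
}

#' @export
print.rr_series <- function(x, ...) {
  n <- length(x$intervals)
  cat(sprintf("rr_series: %d beats, %.1f s, mean RR %.1f ms, %d flagged%s\n",
              n, x$beat_times[n], mean(x$intervals),
              sum(x$flags != "normal"),
              if (x$corrected) ", corrected" else ""))
  invisible(x)
}

#' @export
length.rr_series <- function(x) length(x$intervals)

#' Read an RR-interval recording
#'
#' Reads chest-strap style RR exports.  Two dialects are supported:
#' `plain_ms` is UTF-8 text with one RR interval in milliseconds per line;
#' `timestamped_csv` has a header row with columns `time_s, rr_ms` (extra
#' columns are ignored) and the beat times are taken from the timestamp
#' column.
#'
#' @param path path to the recording.
#' @param dialect `"plain_ms"` (default) or `"timestamped_csv"`.
#' @return an [rr_series()] with all flags `"normal"` and `corrected = FALSE`.
#' @export
read_rr <- function(path, dialect = c("plain_ms", "timestamped_csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("read_rr: file not found: ", path)
  if (dialect == "plain_ms") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L) stop("read_rr: empty file: ", path)
    vals <- suppressWarnings(as.numeric(lines))
    bad <- which(!is.finite(vals) | vals <= 0 | vals >= 5000)
    if (length(bad))
      stop(sprintf("read_rr: invalid RR interval on line %d: '%s'",
                   bad[1L], lines[bad[1L]]))
    rr_series(vals)
  } else {
    df <- utils::read.csv(path, check.names = FALSE)
    need <- c("time_s", "rr_ms")
    if (!all(need %in% names(df)))
      stop("read_rr: timestamped_csv requires columns time_s, rr_ms")
    if (nrow(df) == 0L) stop("read_rr: empty file: ", path)
    vals <- suppressWarnings(as.numeric(df$rr_ms))
    bad <- which(!is.finite(vals) | vals <= 0 | vals >= 5000)
    if (length(bad))
      stop(sprintf("read_rr: invalid RR interval on line %d (data row %d)",
                   bad[1L] + 1L, bad[1L]))
    rr_series(vals, beat_times = as.numeric(df$time_s))
  }
}

#' Write an RR series as a plain millisecond-per-line file
#'
#' @param rr an [rr_series()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rr <- function(rr, path) {
  stopifnot(inherits(rr, "rr_series"))
  writeLines(formatC(rr$intervals, format = "f", digits = 3), path)
  invisible(path)
}
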