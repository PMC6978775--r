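#' Beat series constructor
#'
#' Bundles beat timestamps (seconds from recording start), RR intervals (ms)
#' and instantaneous heart rate (60000/RR, beats/min) into a `beat_series`.
#' Timestamps must be strictly increasing and RR positive.
#'
#' @param t numeric, beat times in seconds.
#' @param rr numeric, RR intervals in milliseconds.
#' @return A `beat_series` object (fields `t`, `rr`, `hr`).
#' @export
beat_series <- function(t, rr) {
  t <- as.numeric(t); rr <- as.numeric(rr)
  if (length(t) != length(rr))
    stop("`t` and `rr` must have equal length")
  if (any(rr <= 0)) stop("RR intervals must be positive")
  if (length(t) > 1L && any(diff(t) <= 0))
    stop("beat timestamps must be strictly increasing")
  structure(list(t = t, rr = rr, hr = 60000 / rr), class = "beat_series")
}

#' @export
print.beat_series <- function(x, ...) {
  cat(sprintf("<beat_series> %d beats, %.1f h, HR %.1f-%.1f bpm (mean %.1f)\n",
              length(x$t), (x$t[length(x$t)] - x$t[1]) / 3600,
              min(x$hr), max(x$hr), mean(x$hr)))
  invisible(x)
}

#' Read an RR-interval recording
#'
#' Reads a plain-text RR file. `"rr-only"` expects one RR interval in
#' milliseconds per line; beat times are reconstructed as the cumulative sum
#' of the intervals. `"time-rr"` expects two whitespace- (or comma-)
#' separated columns, beat time in seconds and RR in milliseconds.
#' Blank lines and lines starting with `#` are skipped.
#'
#' @param path file path.
#' @param dialect `"rr-only"` (default) or `"time-rr"`.
#' @return A [beat_series()].
#' @export
load_rr <- function(path, dialect = c("rr-only", "time-rr")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("RR file not found: ", path)
  raw <- trimws(readLines(path, warn = FALSE))
  keep <- nzchar(raw) & !startsWith(raw, "#")
  lineno <- which(keep)
  raw <- raw[keep]
  if (length(raw) == 0L) stop("empty RR file: ", path)
  if (dialect == "rr-only") {
    rr <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(rr) | rr <= 0)
    if (length(bad))
      stop(sprintf("cannot parse RR value at line %d of %s: '%s'",
                   lineno[bad[1]], path, raw[bad[1]]))
    beat_series(cumsum(rr) / 1000, rr)
  } else {
    parts <- strsplit(raw, "[\t ,;]+")
    ncol_ok <- vapply(parts, length, 1L) >= 2L
    if (any(!ncol_ok))
      stop(sprintf("expected two columns (time_s, rr_ms) at line %d of %s",
                   lineno[which(!ncol_ok)[1]], path))
    t <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 1L)))
    rr <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
    bad <- which(is.na(t) | is.na(rr) | rr <= 0)
    if (length(bad))
      stop(sprintf("cannot parse time/RR values at line %d of %s",
                   lineno[bad[1]], path))
    beat_series(t, rr)
  }
}

#' Write an RR recording in the rr-only dialect
#'
#' One RR interval (milliseconds) per line; round-trips through [load_rr()].
#'
#' @param series a [beat_series()].
#' @param path output file.
#' @export
write_rr <- function(series, path) {
  stopifnot(inherits(series, "beat_series"))
  writeLines(format(series$rr, scientific = FALSE, trim = TRUE), path)
  invisible(path)
}

#' Remove artifact beats by heart-rate bounds
#'
#' Drops beats whose instantaneous heart rate falls outside `[lo, hi]`
#' (defaults 40 and 180 bpm, the standard ambulatory-ECG artifact bounds).
#' Timestamps of retained beats are unchanged; any gaps left behind are
#' closed later by [resample_uniform()].
#'
#' @param series a [beat_series()].
#' @param lo,hi heart-rate bounds in beats/min.
#' @return list with `series` (filtered [beat_series()]) and
#'   `removed_fraction` (proportion of beats dropped).
#' @export
filter_hr <- function(series, lo = 40, hi = 180) {
  stopifnot(inherits(series, "beat_series"))
  if (lo >= hi) stop("`lo` must be smaller than `hi`")
  keep <- series$hr >= lo & series$hr <= hi
  if (!any(keep))
    stop("all beats removed by the [", lo, ", ", hi, "] bpm filter")
  out <- beat_series(series$t[keep], series$rr[keep])
  list(series = out, removed_fraction = mean(!keep))
}

#' Resample instantaneous heart rate onto a uniform grid
#'
#' Linear interpolation of beat-to-beat heart rate onto the grid
#' `t0 + k/fs` covering `[t[1], t[n]]`. A uniform grid is what lets
#' fixed-duration segments and shapelets have identical sample counts, so
#' that the point-by-point sliding distance is defined. Gaps longer than
#' 5 s (e.g. after artifact removal) are bridged by the interpolation, with
#' a warning.
#'
#' @param series a [beat_series()] with at least two beats.
#' @param fs sampling rate in Hz (default 2).
#' @return A `uniform_series` (fields `fs`, `x`, `t0`).
#' @export
resample_uniform <- function(series, fs = 2) {
  stopifnot(inherits(series, "beat_series"))
  if (fs <= 0) stop("`fs` must be positive")
  n_beats <- length(series$t)
  if (n_beats < 2L) stop("need at least two beats to resample")
  gaps <- diff(series$t)
  if (any(gaps > 5))
    warning(sprintf("%d inter-beat gap(s) exceed 5 s (max %.1f s); bridged by interpolation",
                    sum(gaps > 5), max(gaps)))
  span <- series$t[n_beats] - series$t[1]
  n <- floor(span * fs) + 1L
  grid <- series$t[1] + (seq_len(n) - 1L) / fs
  x <- stats::approx(series$t, series$hr, xout = grid, ties = "ordered")$y
  uniform_series(fs = fs, x = x, t0 = series$t[1])
}

#' @rdname resample_uniform
#' @param x heart-rate samples on the uniform grid.
#' @param t0 time of the first sample, seconds.
#' @export
uniform_series <- function(fs, x, t0 = 0) {
  if (fs <= 0) stop("`fs` must be positive")
  if (anyNA(x)) stop("uniform series must not contain missing values")
  structure(list(fs = fs, x = as.numeric(x), t0 = t0),
            class = "uniform_series")
}

#' @export
print.uniform_series <- function(x, ...) {
  cat(sprintf("<uniform_series> %d samples @ %g Hz (%.2f h), range [%.3g, %.3g]\n",
              length(x$x), x$fs, length(x$x) / x$fs / 3600,
              min(x$x), max(x$x)))
  invisible(x)
}

# ---- annotations -----------------------------------------------------------

#' Self-report annotation track
#'
#' Holds the self-reported sleep windows (lights-off to lights-on), as a
#' two-column matrix of `[start_s, end_s)` intervals. Intervals must be
#' non-overlapping and ordered.
#'
#' @param sleep numeric matrix (or 2-vector / list of pairs) of sleep windows
#'   in seconds from recording start.
#' @return An `hrv_annotation` object.
#' @export
annotation <- function(sleep) {
  if (is.null(sleep) || length(sleep) == 0L) {
    sleep <- matrix(numeric(0), ncol = 2)
  } else if (is.list(sleep)) {
    sleep <- do.call(rbind, lapply(sleep, as.numeric))
  } else if (is.null(dim(sleep))) {
    sleep <- matrix(as.numeric(sleep), ncol = 2, byrow = TRUE)
  }
  sleep <- matrix(as.numeric(sleep), ncol = 2)
  if (nrow(sleep)) {
    sleep <- sleep[order(sleep[, 1]), , drop = FALSE]
    if (any(sleep[, 2] <= sleep[, 1]))
      stop("sleep intervals must have end > start")
    if (nrow(sleep) > 1L && any(sleep[-1, 1] < sleep[-nrow(sleep), 2]))
      stop("sleep intervals must not overlap")
  }
  colnames(sleep) <- c("start_s", "end_s")
  structure(list(sleep = sleep), class = "hrv_annotation")
}

#' Read / write annotations as JSON
#'
#' The on-disk form is `{"sleep": [[start_s, end_s], ...]}`.
#'
#' @param path file path.
#' @return [read_annotation()] returns an [annotation()].
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  obj <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  if (is.null(obj$sleep)) stop("annotation JSON lacks a 'sleep' field: ", path)
  annotation(obj$sleep)
}

#' @rdname read_annotation
#' @param ann an [annotation()].
#' @export
write_annotation <- function(ann, path) {
  stopifnot(inherits(ann, "hrv_annotation"))
  jsonlite::write_json(list(sleep = unname(ann$sleep)), path, digits = NA)
  invisible(path)
}

# half-open interval membership [start, end)
in_intervals <- function(x, ints) {
  if (is.null(ints) || nrow(ints) == 0L) return(rep(FALSE, length(x)))
  out <- rep(FALSE, length(x))
  for (i in seq_len(nrow(ints)))
    out <- out | (x >= ints[i, 1] & x < ints[i, 2])
  out
}

#' Per-state mean heart rate summary
#'
#' Mean and SD of the beat-to-beat heart rate inside and outside the
#' annotated sleep windows. The classic preliminary check: the heart
#' beats slower during sleep. With no sleep interval the sleep statistics
#' are `NA` (undefined), never zero.
#'
#' @param series a [beat_series()].
#' @param ann an [annotation()].
#' @return list `mean_hr_sleep`, `mean_hr_awake`, `sd_sleep`, `sd_awake`,
#'   `n_sleep`, `n_awake`.
#' @export
hr_summary <- function(series, ann) {
  stopifnot(inherits(series, "beat_series"), inherits(ann, "hrv_annotation"))
  asleep <- in_intervals(series$t, ann$sleep)
  stat <- function(v) if (length(v)) c(mean(v), stats::sd(v)) else c(NA_real_, NA_real_)
  s <- stat(series$hr[asleep]); a <- stat(series$hr[!asleep])
  list(mean_hr_sleep = s[1], mean_hr_awake = a[1],
       sd_sleep = s[2], sd_awake = a[2],
       n_sleep = sum(asleep), n_awake = sum(!asleep))
}
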