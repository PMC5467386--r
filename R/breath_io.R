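#' Construct a raw airflow signal
#'
#' Container for a single-channel nasal-cannula airflow trace. Positive
#' values are inspiration; `baseline` is the amplitude treated as zero flow
#' (pressure-derived flow signals are usually already zero-centred).
#'
#' @param samples Numeric vector of airflow amplitudes (arbitrary units).
#' @param sampling_rate Sampling rate in Hz; must be positive.
#' @param baseline Amplitude offset treated as zero flow. Default 0.
#' @return An object of class `flow_signal` with fields `samples`,
#'   `sampling_rate` and `baseline`.
#' @export
flow_signal <- function(samples, sampling_rate, baseline = 0) {
  samples <- as.numeric(samples)
  if (length(samples) == 0L)
    stop("'samples' must be non-empty", call. = FALSE)
  if (!all(is.finite(samples)))
    stop("'samples' must all be finite", call. = FALSE)
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      !is.finite(sampling_rate) || sampling_rate <= 0)
    stop("'sampling_rate' must be a single positive number", call. = FALSE)
  if (!is.numeric(baseline) || length(baseline) != 1L || !is.finite(baseline))
    stop("'baseline' must be a single finite number", call. = FALSE)
  structure(
    list(samples = samples, sampling_rate = sampling_rate, baseline = baseline),
    class = "flow_signal"
  )
}

#' @export
print.flow_signal <- function(x, ...) {
  cat(sprintf("<flow_signal: %d samples at %g Hz (%.1f s), baseline %g>\n",
              length(x$samples), x$sampling_rate,
              length(x$samples) / x$sampling_rate, x$baseline))
  invisible(x)
}

#' Read an airflow trace from a delimited text file
#'
#' Two dialects are supported: a two-column `time,flow` file (header
#' optional; the sampling rate is inferred from the median time step) and a
#' one-value-per-line flow file for which `sampling_rate` must be supplied.
#' Comma, tab and whitespace delimiters are accepted.
#'
#' @param path Path to the file.
#' @param format One of `"auto"`, `"two-column"`, `"flow-only"`. With
#'   `"auto"`, two numeric columns select the two-column dialect.
#' @param sampling_rate Sampling rate in Hz; required for the flow-only
#'   dialect, ignored (and checked against the time column) otherwise.
#' @param baseline Amplitude treated as zero flow. Default 0.
#' @return A [flow_signal()].
#' @export
load_flow_signal <- function(path,
                             format = c("auto", "two-column", "flow-only"),
                             sampling_rate = NULL, baseline = 0) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop(sprintf("input file '%s' does not exist", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- trimws(lines[keep])
  if (length(lines) == 0L)
    stop(sprintf("input file '%s' is empty", path), call. = FALSE)

  fields <- strsplit(lines, "[,\t ]+")
  ncol <- length(fields[[1L]])

  # optional header: first row entirely non-numeric
  first <- suppressWarnings(as.numeric(fields[[1L]]))
  start <- if (all(is.na(first))) 2L else 1L
  if (start > length(fields))
    stop(sprintf("input file '%s' has no data rows", path), call. = FALSE)

  rows <- fields[start:length(fields)]
  nums <- lapply(rows, function(f) suppressWarnings(as.numeric(f)))
  bad <- which(vapply(nums, function(v) length(v) != ncol || !all(is.finite(v)),
                      logical(1L)))
  if (length(bad))
    stop(sprintf("non-numeric or malformed value on line %d of '%s'",
                 line_no[start - 1L + bad[1L]], path), call. = FALSE)
  mat <- do.call(rbind, nums)

  if (format == "auto")
    format <- if (ncol >= 2L) "two-column" else "flow-only"

  if (format == "two-column") {
    if (ncol < 2L)
      stop("two-column format requires a time and a flow column", call. = FALSE)
    tm <- mat[, 1L]
    flow <- mat[, 2L]
    dt <- diff(tm)
    if (length(dt) == 0L || any(dt <= 0))
      stop("time column must be strictly increasing", call. = FALSE)
    med <- stats::median(dt)
    if (max(abs(dt - med)) > 0.01 * med)
      stop("non-uniform time steps (beyond 1% of the median step)",
           call. = FALSE)
    flow_signal(flow, 1 / med, baseline)
  } else {
    if (is.null(sampling_rate))
      stop("flow-only format requires 'sampling_rate'", call. = FALSE)
    flow_signal(mat[, 1L], sampling_rate, baseline)
  }
}

# Zero-phase filtering with odd reflection padding at both ends.
# signal::filtfilt alone starts each pass from zero state, which corrupts
# the first/last ~1 s of a breath trace.
zero_phase <- function(filt, x, npad) {
  n <- length(x)
  npad <- min(npad, n - 1L)
  if (npad < 1L) return(as.numeric(signal::filtfilt(filt, x)))
  pre <- 2 * x[1L] - x[seq(npad + 1L, 2L)]
  post <- 2 * x[n] - x[seq(n - 1L, n - npad)]
  y <- as.numeric(signal::filtfilt(filt, c(pre, x, post)))
  y[(npad + 1L):(npad + n)]
}

#' Low-pass filter an airflow signal
#'
#' Zero-phase 4th-order Butterworth low-pass filter (applied
#' forward-backward with reflection padding), preserving breath onset
#' timing. The 2 Hz default suppresses snore noise while leaving the
#' sub-1 Hz respiratory content intact.
#'
#' @param x A [flow_signal()].
#' @param cutoff Cut-off frequency in Hz; must be below the Nyquist
#'   frequency. Default 2.
#' @param order Butterworth order. Default 4.
#' @return A filtered [flow_signal()] of the same length and rate.
#' @export
lowpass_filter <- function(x, cutoff = 2.0, order = 4L) {
  stopifnot(inherits(x, "flow_signal"))
  nyq <- x$sampling_rate / 2
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0 || cutoff >= nyq)
    stop(sprintf("'cutoff' must lie in (0, %g) Hz (below Nyquist)", nyq),
         call. = FALSE)
  bf <- signal::butter(order, cutoff / nyq, type = "low")
  npad <- max(3L * ceiling(x$sampling_rate / cutoff), 3L * (order + 1L))
  flow_signal(zero_phase(bf, x$samples, npad), x$sampling_rate, x$baseline)
}

#' Construct a single inspiratory breath segment
#'
#' Sample indices are 0-based with a half-open span: the breath covers
#' samples `start_index` (inclusive) to `end_index` (exclusive).
#'
#' @param start_index 0-based first sample of the inspiration.
#' @param end_index 0-based sample one past the inspiration.
#' @param samples Airflow amplitudes of the segment.
#' @return An object of class `breath`.
#' @export
breath <- function(start_index, end_index, samples) {
  if (end_index <= start_index)
    stop("'end_index' must exceed 'start_index'", call. = FALSE)
  samples <- as.numeric(samples)
  if (length(samples) != end_index - start_index)
    stop("'samples' length must equal end_index - start_index", call. = FALSE)
  structure(list(start_index = start_index, end_index = end_index,
                 samples = samples), class = "breath")
}

#' Segment a flow trace into inspiratory breaths
#'
#' An inspiration is a maximal run of positive baseline-relative flow,
#' entered at a negative-to-positive crossing and left at the return
#' crossing. Runs shorter than `min_duration` are treated as noise-driven
#' zero crossings and discarded.
#'
#' @param x A [flow_signal()] (baseline-relative; the signal must cross zero).
#' @param min_duration Minimum inspiration duration in seconds. Default 0.5.
#' @return A list of [breath()] objects in temporal order (possibly empty).
#' @export
segment_inspirations <- function(x, min_duration = 0.5) {
  stopifnot(inherits(x, "flow_signal"))
  pos <- (x$samples - x$baseline) > 0
  r <- rle(pos)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & (r$lengths / x$sampling_rate >= min_duration)
  mapply(function(s, e) breath(s - 1L, e, x$samples[s:e] - x$baseline),
         starts[keep], ends[keep], SIMPLIFY = FALSE)
}

#' Construct a normalized breath
#'
#' The canonical per-breath representation: 100 amplitudes on an equally
#' spaced time grid over the unit interval, with amplitude range exactly
#' \[0, 1\].
#'
#' @param values Numeric vector of 100 amplitudes with min 0 and max 1.
#' @return An object of class `normalized_breath` with fields `values` and
#'   `grid`.
#' @export
normalized_breath <- function(values) {
  values <- as.numeric(values)
  if (length(values) != 100L)
    stop("a normalized breath must have exactly 100 values", call. = FALSE)
  if (!all(is.finite(values)))
    stop("normalized breath values must be finite", call. = FALSE)
  if (abs(min(values)) > 1e-9 || abs(max(values) - 1) > 1e-9)
    stop("normalized breath values must have min 0 and max 1", call. = FALSE)
  structure(list(values = values, grid = seq(0, 1, length.out = 100L)),
            class = "normalized_breath")
}

#' @export
print.normalized_breath <- function(x, ...) {
  cat(sprintf("<normalized_breath: peak at grid index %d (t = %.3f)>\n",
              which.max(x$values) - 1L, x$grid[which.max(x$values)]))
  invisible(x)
}

# Accept a normalized_breath or a bare 100-vector everywhere downstream.
as_normalized_breath <- function(x) {
  if (inherits(x, "normalized_breath")) return(x)
  if (is.numeric(x)) return(normalized_breath(x))
  stop("expected a 'normalized_breath' or a numeric vector of 100 values",
       call. = FALSE)
}

#' Normalize a breath to the 100-point unit square
#'
#' Linearly interpolates the inspiration onto 100 equally spaced points of
#' normalized time \[0, 1\], then rescales the amplitude affinely so the
#' minimum is 0 and the maximum is 1. Amplitude rescaling happens after
#' resampling so the extremes are exact on the final grid.
#'
#' @param x A [breath()] or numeric vector of at least 4 samples with
#'   non-constant amplitude.
#' @return A [normalized_breath()].
#' @export
normalize_breath <- function(x) {
  v <- if (inherits(x, "breath")) x$samples else as.numeric(x)
  n <- length(v)
  if (n < 4L)
    stop("breath too short to normalize (need >= 4 samples)", call. = FALSE)
  if (!all(is.finite(v)))
    stop("breath samples must be finite", call. = FALSE)
  rng <- max(v) - min(v)
  if (rng == 0)
    stop("degenerate breath: constant amplitude (zero range)", call. = FALSE)
  g <- seq(0, 1, length.out = 100L)
  vi <- stats::approx(seq(0, 1, length.out = n), v, xout = g)$y
  vi <- (vi - min(vi)) / (max(vi) - min(vi))
  normalized_breath(vi)
}

#' Tabulate segmented breaths
#'
#' @param breaths List of [breath()] objects.
#' @param sampling_rate Sampling rate in Hz used to convert indices to
#'   seconds.
#' @return A data frame with columns `breath_id`, `start_time_s`,
#'   `end_time_s`, `n_samples`.
#' @export
breath_table <- function(breaths, sampling_rate) {
  data.frame(
    breath_id = seq_along(breaths),
    start_time_s = vapply(breaths, function(b) b$start_index, numeric(1)) /
      sampling_rate,
    end_time_s = vapply(breaths, function(b) b$end_index, numeric(1)) /
      sampling_rate,
    n_samples = vapply(breaths, function(b) length(b$samples), integer(1))
  )
}
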