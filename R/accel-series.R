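#' Tri-axial accelerometer series
#'
#' The pipeline's input container: per-axis acceleration in m/s^2, sample
#' timestamps in seconds, and the sensor's nominal sampling frequency in Hz.
#' When `timestamps` is `NULL` they are synthesized as `(i - 1) / frequency_hz`
#' seconds, the rule used for datasets that ship no timing information.
#'
#' @param x,y,z Numeric vectors of per-axis acceleration (m/s^2), equal length.
#' @param timestamps Numeric vector of sample times in seconds, strictly
#'   increasing, or `NULL` to synthesize from `frequency_hz`.
#' @param frequency_hz Nominal sampling rate in Hz (> 0).
#' @param label Optional ground-truth tag (`"fall"` / `"non-fall"`), or `NULL`.
#'
#' @return An object of class `accel_series`: a list with elements `timestamps`,
#'   `x`, `y`, `z`, `frequency_hz`, `label`.
#' @examples
#' s <- accel_series(x = c(0, 3), y = c(0, 4), z = c(9.80665, 12),
#'                   frequency_hz = 100)
#' compute_magnitudes(s)
#' @export
accel_series <- function(x, y, z, timestamps = NULL, frequency_hz, label = NULL) {
  x <- as.double(x); y <- as.double(y); z <- as.double(z)
  n <- length(x)
  if (n < 1L) {
    stop("accel_series requires at least one sample", call. = FALSE)
  }
  if (length(y) != n || length(z) != n) {
    stop("x, y and z must have the same length", call. = FALSE)
  }
  if (!is.numeric(frequency_hz) || length(frequency_hz) != 1L ||
      !is.finite(frequency_hz) || frequency_hz <= 0) {
    stop("frequency_hz must be a single positive number", call. = FALSE)
  }
  if (is.null(timestamps)) {
    timestamps <- (seq_len(n) - 1) / frequency_hz
  } else {
    timestamps <- as.double(timestamps)
    if (length(timestamps) != n) {
      stop("timestamps must match the axis length", call. = FALSE)
    }
    if (anyNA(timestamps) || (n > 1L && any(diff(timestamps) <= 0))) {
      stop("timestamps must be strictly increasing", call. = FALSE)
    }
  }
  if (anyNA(x) || anyNA(y) || anyNA(z)) {
    stop("acceleration values must not contain NA", call. = FALSE)
  }
  structure(
    list(timestamps = timestamps, x = x, y = y, z = z,
         frequency_hz = as.double(frequency_hz), label = label),
    class = "accel_series"
  )
}

#' @export
print.accel_series <- function(x, ...) {
  cat(sprintf(
    "<accel_series> %d samples @ %g Hz, %.3f s%s\n",
    length(x$x), x$frequency_hz,
    x$timestamps[length(x$timestamps)] - x$timestamps[1L],
    if (is.null(x$label)) "" else paste0(", label: ", x$label)
  ))
  invisible(x)
}

#' Number of samples in an accelerometer series
#' @param series An [accel_series()].
#' @return Integer sample count.
#' @export
n_samples <- function(series) {
  stopifnot(inherits(series, "accel_series"))
  length(series$x)
}

#' Sum vector magnitude of a tri-axial series
#'
#' The orientation-invariant scalar the detector works on:
#' `sqrt(x^2 + y^2 + z^2)` per sample.
#'
#' @param series An [accel_series()].
#' @return Numeric vector of magnitudes (m/s^2), same length as the series.
#' @export
compute_magnitudes <- function(series) {
  if (!inherits(series, "accel_series")) {
    stop("compute_magnitudes expects an accel_series", call. = FALSE)
  }
  sqrt(series$x^2 + series$y^2 + series$z^2)
}

#' Frequency-normalized pseudo-timestamps ("entries")
#'
#' Every temporal threshold in the detector is expressed in entry units rather
#' than seconds, so the same threshold values work at any sampling rate. The
#' first entry is 0 and each subsequent one advances by
#' `(t[i] - t[i-1]) / 10 + 100 / frequency_hz`, i.e. a fixed per-sample step of
#' `100 / frequency_hz` plus a small correction proportional to the actual time
#' gap. At ideal second-valued timestamps this advances ~100.1 entry units per
#' second at any frequency, so 100 entry units correspond to about one second.
#'
#' @param timestamps Numeric vector of sample times in seconds, strictly
#'   increasing.
#' @param frequency_hz Nominal sampling rate in Hz (> 0).
#' @return Numeric non-decreasing vector of entries, `entries[1] == 0`.
#' @examples
#' compute_entries(c(0, 0.01, 0.02), 100)  # 0, 1.001, 2.002
#' @export
compute_entries <- function(timestamps, frequency_hz) {
  timestamps <- as.double(timestamps)
  n <- length(timestamps)
  if (n < 1L) stop("timestamps must be non-empty", call. = FALSE)
  if (!is.numeric(frequency_hz) || length(frequency_hz) != 1L ||
      !is.finite(frequency_hz) || frequency_hz <= 0) {
    stop("frequency_hz must be a single positive number", call. = FALSE)
  }
  if (n == 1L) return(0)
  d <- diff(timestamps)
  if (anyNA(d) || any(d <= 0)) {
    stop("timestamps must be strictly increasing", call. = FALSE)
  }
  c(0, cumsum(d / 10 + 100 / frequency_hz))
}

#' Magnitude series: the detector's working representation
#'
#' Bundles per-sample magnitudes, entries and timestamps.
#'
#' @param series An [accel_series()].
#' @return An object of class `magnitude_series`: a list with `magnitudes`,
#'   `entries`, `timestamps`, `frequency_hz`.
#' @export
magnitude_series <- function(series) {
  m <- compute_magnitudes(series)
  e <- compute_entries(series$timestamps, series$frequency_hz)
  structure(
    list(magnitudes = m, entries = e, timestamps = series$timestamps,
         frequency_hz = series$frequency_hz),
    class = "magnitude_series"
  )
}

#' @export
print.magnitude_series <- function(x, ...) {
  cat(sprintf("<magnitude_series> %d samples, magnitude range [%.2f, %.2f] m/s^2\n",
              length(x$magnitudes), min(x$magnitudes), max(x$magnitudes)))
  invisible(x)
}
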