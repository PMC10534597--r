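#' A labeled trial: one recording with a ground-truth class
#'
#' @param series An [accel_series()].
#' @param label `"fall"` or `"non-fall"`.
#' @param sub_class Free-text activity name, or `NULL`.
#' @param dataset_id,subject_id,trial_id Identifiers, or `NULL`.
#' @return An object of class `fall_trial`.
#' @export
fall_trial <- function(series, label = NULL, sub_class = NULL,
                       dataset_id = NULL, subject_id = NULL, trial_id = NULL) {
  stopifnot(inherits(series, "accel_series"))
  if (!is.null(label) && !label %in% c("fall", "non-fall")) {
    stop("label must be \"fall\" or \"non-fall\"", call. = FALSE)
  }
  structure(
    list(series = series, label = label, sub_class = sub_class,
         dataset_id = dataset_id, subject_id = subject_id,
         trial_id = trial_id),
    class = "fall_trial"
  )
}

#' @export
print.fall_trial <- function(x, ...) {
  cat(sprintf("<fall_trial> %s%s: %d samples @ %g Hz, label %s\n",
              x$dataset_id %||% "?", if (is.null(x$trial_id)) "" else
                paste0("/", x$trial_id),
              n_samples(x$series), x$series$frequency_hz,
              x$label %||% "<none>"))
  invisible(x)
}

#' CSV dialect descriptions for public fall-detection dataset layouts
#'
#' The public datasets do not share a column layout, so readers are driven by
#' a small dialect object: which columns (by name or 1-based index) hold the
#' axes, the optional timestamp and label columns, the acceleration unit, and
#' the nominal sampling frequency used to synthesize timestamps when the file
#' has none. Shipped defaults follow the documented layouts of the KFall-, UR-
#' and MMsys-style datasets but every field can be overridden.
#'
#' `kfall_dialect()`: per-trial files, acceleration in g (converted to m/s^2
#' by 9.807), explicit timestamp column, 100 Hz.
#' `ur_dialect()`: per-trial files, no timing information (timestamps
#' synthesized at 60 Hz), axes in columns 2–4.
#' `mmsys_dialect()`: one continuous per-subject file with a numeric class
#' label per sample, timestamps synthesized at 100 Hz.
#'
#' @param name Dialect name.
#' @param x,y,z Axis columns (character names or numeric indices).
#' @param time Timestamp column, or `NULL` to synthesize.
#' @param label Per-sample label column, or `NULL`.
#' @param unit `"ms2"` or `"g"` (the latter converted by 9.807).
#' @param frequency_hz Nominal sampling rate (Hz).
#' @return An object of class `csv_dialect`.
#' @export
csv_dialect <- function(name, x, y, z, time = NULL, label = NULL,
                        unit = c("ms2", "g"), frequency_hz = NULL) {
  unit <- match.arg(unit)
  structure(list(name = name, x = x, y = y, z = z, time = time,
                 label = label, unit = unit, frequency_hz = frequency_hz),
            class = "csv_dialect")
}

#' @rdname csv_dialect
#' @export
kfall_dialect <- function() {
  csv_dialect("kfall", x = "AccX", y = "AccY", z = "AccZ",
              time = "TimeStamp(s)", unit = "g", frequency_hz = 100)
}

#' @rdname csv_dialect
#' @export
ur_dialect <- function() {
  csv_dialect("ur", x = 2, y = 3, z = 4, unit = "ms2", frequency_hz = 60)
}

#' @rdname csv_dialect
#' @export
mmsys_dialect <- function() {
  csv_dialect("mmsys", x = "x", y = "y", z = "z", label = "label",
              unit = "ms2", frequency_hz = 100)
}

.read_raw_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- tryCatch(
    read.csv(path, check.names = FALSE, stringsAsFactors = FALSE),
    error = function(e) stop("empty or unparseable file: ", path, call. = FALSE)
  )
  if (nrow(df) == 0L) stop("empty stream: no samples in ", path, call. = FALSE)
  df
}

.dialect_column <- function(df, col, what, path) {
  if (is.numeric(col)) {
    if (col < 1 || col > ncol(df)) {
      stop(sprintf("column index %d (%s) out of range in %s", col, what, path),
           call. = FALSE)
    }
    return(df[[col]])
  }
  if (!col %in% names(df)) {
    stop(sprintf("column '%s' (%s) not found in %s", col, what, path),
         call. = FALSE)
  }
  df[[col]]
}

.numeric_column <- function(vals, what, path) {
  num <- suppressWarnings(as.numeric(vals))
  bad <- which(is.na(num))
  if (length(bad)) {
    stop(sprintf("non-numeric value '%s' at row %d of column %s in %s",
                 as.character(vals[bad[1L]]), bad[1L], what, path),
         call. = FALSE)
  }
  num
}

#' Read one per-trial CSV file
#'
#' Reads a KFall- or UR-style per-trial recording. Acceleration in g is
#' converted to m/s^2 (factor 9.807); when the dialect names no timestamp
#' column, timestamps are synthesized as `(i - 1) / frequency_hz` seconds.
#'
#' @param path CSV file path.
#' @param dialect A [csv_dialect()].
#' @param frequency_hz Overrides the dialect's sampling rate, if given.
#' @param label,sub_class,subject_id Ground-truth metadata for the trial.
#' @return A [fall_trial()].
#' @export
read_trial_csv <- function(path, dialect = kfall_dialect(),
                           frequency_hz = NULL, label = NULL,
                           sub_class = NULL, subject_id = NULL) {
  stopifnot(inherits(dialect, "csv_dialect"))
  df <- .read_raw_csv(path)
  f <- frequency_hz %||% dialect$frequency_hz
  if (is.null(f)) stop("no sampling frequency available", call. = FALSE)
  ax <- lapply(c(x = "x", y = "y", z = "z"), function(a) {
    .numeric_column(.dialect_column(df, dialect[[a]], a, path), a, path)
  })
  if (dialect$unit == "g") ax <- lapply(ax, function(v) v * kfall_g)
  timestamps <- NULL
  if (!is.null(dialect$time)) {
    timestamps <- .numeric_column(
      .dialect_column(df, dialect$time, "time", path), "time", path)
  }
  series <- accel_series(ax$x, ax$y, ax$z, timestamps = timestamps,
                         frequency_hz = f, label = label)
  fall_trial(series, label = label, sub_class = sub_class,
             dataset_id = dialect$name, subject_id = subject_id,
             trial_id = basename(path))
}

#' Class table for MMsys-style per-sample labels
#'
#' Maps the numeric per-sample labels of the MMsys-style continuous files to
#' class names and a fall / non-fall / near-fall polarity. Whether "near fall"
#' counts as a positive is left to the evaluator (see
#' [score_stream()]'s `positive_labels`).
#'
#' @return A data frame with columns `label`, `class`, `polarity`.
#' @export
mmsys_classes <- function() {
  data.frame(
    label = c(1:13, 15L),
    class = c("Standing", "Fall forward", "Lying", "Sitting on a bed",
              "Sitting on a chair", "Fall backward", "Near fall", "Walking",
              "Crouching", "Fall right", "Fall left", "Real fall forward",
              "Real fall backward", "Ascending and Descending a staircase"),
    polarity = c("non-fall", "fall", "non-fall", "non-fall", "non-fall",
                 "fall", "near-fall", "non-fall", "non-fall", "fall", "fall",
                 "fall", "fall", "non-fall"),
    stringsAsFactors = FALSE
  )
}

#' Read a continuous labeled stream CSV (MMsys-style)
#'
#' One file holds a subject's whole recording with a numeric class label per
#' sample; timestamps are synthesized from the sampling frequency and runs of
#' equal labels are merged into closed `[start_index, end_index]` intervals.
#'
#' @param path CSV file path.
#' @param dialect A [csv_dialect()] with a `label` column.
#' @param frequency_hz Overrides the dialect's sampling rate, if given.
#' @param classes Label table, see [mmsys_classes()].
#' @return An object of class `labeled_stream`: a list with `series` (an
#'   [accel_series()]) and `intervals` (data frame `start_index`,
#'   `end_index`, `label`, `class`, `polarity`).
#' @export
read_stream_csv <- function(path, dialect = mmsys_dialect(),
                            frequency_hz = NULL, classes = mmsys_classes()) {
  stopifnot(inherits(dialect, "csv_dialect"))
  if (is.null(dialect$label)) {
    stop("stream dialect must name a label column", call. = FALSE)
  }
  df <- .read_raw_csv(path)
  f <- frequency_hz %||% dialect$frequency_hz
  if (is.null(f)) stop("no sampling frequency available", call. = FALSE)
  ax <- lapply(c(x = "x", y = "y", z = "z"), function(a) {
    .numeric_column(.dialect_column(df, dialect[[a]], a, path), a, path)
  })
  if (dialect$unit == "g") ax <- lapply(ax, function(v) v * kfall_g)
  lab <- .dialect_column(df, dialect$label, "label", path)
  unknown <- setdiff(unique(lab), classes$label)
  if (length(unknown)) {
    stop(sprintf("unknown label value(s) %s in %s; known labels: %s",
                 paste(unknown, collapse = ", "), path,
                 paste(classes$label, collapse = ", ")), call. = FALSE)
  }
  r <- rle(as.vector(lab))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  m <- match(r$values, classes$label)
  intervals <- data.frame(start_index = starts, end_index = ends,
                          label = r$values, class = classes$class[m],
                          polarity = classes$polarity[m],
                          stringsAsFactors = FALSE)
  series <- accel_series(ax$x, ax$y, ax$z, frequency_hz = f)
  structure(list(series = series, intervals = intervals),
            class = "labeled_stream")
}

#' @export
print.labeled_stream <- function(x, ...) {
  cat(sprintf("<labeled_stream> %d samples, %d interval(s), classes: %s\n",
              n_samples(x$series), nrow(x$intervals),
              paste(unique(x$intervals$class), collapse = ", ")))
  invisible(x)
}

#' Write accepted falls to a detection CSV
#'
#' One row per accepted fall, ordered by start time:
#' `id, start_time_s, end_time_s, start_entry, end_entry, peak_magnitude`.
#' An empty report yields a header-only file.
#'
#' @param report A `fall_report` from [validate_falls()] / [find_falls()].
#' @param path Output file path.
#' @param id Trial/stream identifier written in the first column.
#' @return `path`, invisibly.
#' @export
write_detections <- function(report, path, id = "trial") {
  stopifnot(inherits(report, "fall_report"))
  acc <- report$accepted
  out <- data.frame(id = rep(id, nrow(acc)),
                    start_time_s = acc$start_time,
                    end_time_s = acc$end_time,
                    start_entry = acc$start_entry,
                    end_entry = acc$end_entry,
                    peak_magnitude = acc$peak_magnitude,
                    stringsAsFactors = FALSE)
  out <- out[order(out$start_time_s), , drop = FALSE]
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write an accelerometer series as a dialect-shaped CSV
#'
#' Inverse of [read_trial_csv()]: emits a CSV laid out per the dialect
#' (acceleration divided by 9.807 for g-unit dialects). Numbers are printed
#' with 17 significant digits so m/s^2 dialects round-trip bit-exactly.
#'
#' @param series An [accel_series()] or [fall_trial()].
#' @param path Output file path.
#' @param dialect A [csv_dialect()] with named (character) columns.
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(series, path, dialect = kfall_dialect()) {
  if (inherits(series, "fall_trial")) series <- series$series
  stopifnot(inherits(series, "accel_series"), inherits(dialect, "csv_dialect"))
  cols <- c(dialect$time, dialect$x, dialect$y, dialect$z)
  if (!is.character(cols)) {
    stop("write_trial_csv needs a dialect with named columns", call. = FALSE)
  }
  fmt <- function(v) sprintf("%.17g", v)
  conv <- if (dialect$unit == "g") 1 / kfall_g else 1
  out <- list()
  if (!is.null(dialect$time)) out[[dialect$time]] <- fmt(series$timestamps)
  out[[dialect$x]] <- fmt(series$x * conv)
  out[[dialect$y]] <- fmt(series$y * conv)
  out[[dialect$z]] <- fmt(series$z * conv)
  out <- as.data.frame(out, check.names = FALSE, stringsAsFactors = FALSE)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
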