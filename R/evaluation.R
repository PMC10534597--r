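#' Confusion-matrix counts
#'
#' @param tp,fp,tn,fn Non-negative counts.
#' @return An object of class `confusion_counts`. Objects add with `+`.
#' @export
confusion_counts <- function(tp = 0, fp = 0, tn = 0, fn = 0) {
  v <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(v < 0) || anyNA(v)) stop("counts must be non-negative", call. = FALSE)
  structure(as.list(v), class = "confusion_counts")
}

#' @export
`+.confusion_counts` <- function(e1, e2) {
  confusion_counts(e1$tp + e2$tp, e1$fp + e2$fp, e1$tn + e2$tn, e1$fn + e2$fn)
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP %g  FP %g  TN %g  FN %g\n",
              x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

#' Score one labeled trial
#'
#' Per-trial accounting with the multiple-detection rule: on a fall trial, the
#' first detection is the TP and every extra detection is an FP; zero
#' detections is an FN. On a non-fall trial every detection is an FP; zero
#' detections is a TN.
#'
#' @param label `"fall"` or `"non-fall"`.
#' @param n_detections Number of accepted falls reported for the trial.
#' @return A [confusion_counts()] increment.
#' @examples
#' score_trial("fall", 2)  # TP 1, FP 1
#' @export
score_trial <- function(label, n_detections) {
  label <- match.arg(label, c("fall", "non-fall"))
  k <- n_detections
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 0 || k != round(k)) {
    stop("n_detections must be a single non-negative integer", call. = FALSE)
  }
  if (label == "fall") {
    if (k == 0) confusion_counts(fn = 1) else confusion_counts(tp = 1, fp = k - 1)
  } else {
    if (k == 0) confusion_counts(tn = 1) else confusion_counts(fp = k)
  }
}

#' Score detections against ground-truth intervals of a continuous stream
#'
#' Overlap is >= 1 shared sample. Each detection either claims the first
#' still-unmatched fall interval it overlaps (TP) or counts as an FP — which
#' covers detections overlapping no fall interval and extra detections on an
#' already-matched fall. Unmatched fall intervals are FNs; non-fall intervals
#' untouched by any detection are TNs.
#'
#' @param intervals Data frame with `start_index`, `end_index` and either a
#'   `polarity` column or a `label` column (labels in `positive_labels` count
#'   as falls).
#' @param detections Data frame with `start_index`, `end_index` (e.g. the
#'   `accepted` table of a `fall_report`).
#' @param positive_labels Labels treated as positive ground truth, used when
#'   `intervals` has no `polarity` column; also applied to `polarity` itself,
#'   so a "near fall" class can be scored as positive or negative by choice.
#' @return A [confusion_counts()].
#' @export
score_stream <- function(intervals, detections, positive_labels = "fall") {
  pol <- if ("polarity" %in% names(intervals)) intervals$polarity
         else intervals$label
  if (is.null(pol)) {
    stop("intervals must have a polarity or label column", call. = FALSE)
  }
  is_fall <- pol %in% positive_labels
  fall_iv <- which(is_fall)
  matched <- rep(FALSE, length(fall_iv))
  tp <- 0; fp <- 0
  if (nrow(detections)) {
    detections <- detections[order(detections$start_index), , drop = FALSE]
  }
  overlaps <- function(i, d) {
    intervals$start_index[i] <= detections$end_index[d] &
      detections$start_index[d] <= intervals$end_index[i]
  }
  for (d in seq_len(nrow(detections))) {
    ov <- fall_iv[overlaps(fall_iv, d)]
    free <- which(fall_iv %in% ov & !matched)
    if (length(free)) {
      matched[free[1L]] <- TRUE
      tp <- tp + 1
    } else {
      fp <- fp + 1
    }
  }
  fn <- sum(!matched)
  tn <- 0
  for (i in which(!is_fall)) {
    touched <- nrow(detections) > 0 && any(overlaps(i, seq_len(nrow(detections))))
    if (!touched) tn <- tn + 1
  }
  confusion_counts(tp, fp, tn, fn)
}

#' Accuracy, sensitivity, specificity, precision
#'
#' The four standard quotients of the confusion matrix, as fractions in
#' \[0, 1\]. A metric whose denominator is zero is `NA` (not available), never
#' reported as 0.
#'
#' @param counts A [confusion_counts()].
#' @return An object of class `metric_set` with elements `accuracy`,
#'   `sensitivity`, `specificity`, `precision`.
#' @export
compute_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  q <- function(num, den) if (den == 0) NA_real_ else num / den
  structure(
    list(accuracy = q(counts$tp + counts$tn,
                      counts$tp + counts$fp + counts$tn + counts$fn),
         sensitivity = q(counts$tp, counts$tp + counts$fn),
         specificity = q(counts$tn, counts$tn + counts$fp),
         precision = q(counts$tp, counts$tp + counts$fp)),
    class = "metric_set"
  )
}

#' @export
print.metric_set <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "NA" else sprintf("%.2f%%", 100 * v)
  cat(sprintf("<metric_set> accuracy %s | sensitivity %s | specificity %s | precision %s\n",
              fmt(x$accuracy), fmt(x$sensitivity), fmt(x$specificity),
              fmt(x$precision)))
  invisible(x)
}

.trial_counts <- function(trials, thresholds, apply_final_checks = TRUE) {
  total <- confusion_counts()
  for (tr in trials) {
    rep <- find_falls(tr$series, thresholds, apply_final_checks)
    total <- total + score_trial(tr$label, nrow(rep$accepted))
  }
  total
}

#' Sweep a grid of threshold combinations over labeled trials
#'
#' Runs the full pipeline once per grid row, accumulating per-trial confusion
#' counts, and reports the four metrics plus the false positive rate
#' (`fpr = 1 - specificity`) per combination, in grid order.
#'
#' @param grid Data frame whose columns are [threshold_set()] argument names.
#' @param trials List of [fall_trial()] objects with labels.
#' @param base A [threshold_set()] supplying the unswept values.
#' @return A data frame: the grid columns, `tp fp tn fn`, the four metrics
#'   (fractions) and `fpr`.
#' @export
sweep_thresholds <- function(grid, trials, base = threshold_set()) {
  if (!is.data.frame(grid) || nrow(grid) == 0L) {
    stop("grid must be a non-empty data frame", call. = FALSE)
  }
  bad <- setdiff(names(grid), names(formals(threshold_set)))
  if (length(bad)) {
    stop("unknown threshold column(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  base_args <- Filter(Negate(is.null), unclass(base))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    over <- lapply(grid[i, , drop = FALSE], function(col) col[[1L]])
    th <- do.call(threshold_set, utils::modifyList(base_args, over))
    counts <- .trial_counts(trials, th)
    met <- compute_metrics(counts)
    cbind(grid[i, , drop = FALSE],
          data.frame(tp = counts$tp, fp = counts$fp, tn = counts$tn,
                     fn = counts$fn,
                     accuracy = met$accuracy, sensitivity = met$sensitivity,
                     specificity = met$specificity, precision = met$precision,
                     fpr = 1 - met$specificity))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-sub-class tallies, with and without the final checks
#'
#' Reproduces the per-class accounting layout of the method's result tables:
#' for every sub-class, the trial total, correct detections ("true"), errors
#' ("false"), and the errors obtained when the final acceptance checks are
#' disabled ("false_2") — quantifying how much the last validation stage
#' contributes. On a fall class, errors are missed falls plus surplus
#' detections; on a non-fall class, every detection is an error.
#'
#' @param trials List of [fall_trial()] objects with `label` and `sub_class`.
#' @param thresholds A [threshold_set()].
#' @return A data frame with one row per sub-class: `sub_class`, `label`,
#'   `total`, `true`, `false`, `false_2`.
#' @export
tally_subclasses <- function(trials, thresholds = threshold_set()) {
  per <- lapply(trials, function(tr) {
    det <- detect_falls(tr$series, thresholds)
    k <- nrow(validate_falls(det, apply_final_checks = TRUE)$accepted)
    k2 <- nrow(validate_falls(det, apply_final_checks = FALSE)$accepted)
    data.frame(sub_class = tr$sub_class %||% "<none>", label = tr$label,
               k = k, k2 = k2, stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  err <- function(label, k) {
    if (label == "fall") sum(k == 0) + sum(pmax(k - 1, 0)) else sum(k)
  }
  out <- lapply(split(per, per$sub_class), function(g) {
    data.frame(sub_class = g$sub_class[1L], label = g$label[1L],
               total = nrow(g),
               true = if (g$label[1L] == "fall") sum(g$k >= 1) else sum(g$k == 0),
               false = err(g$label[1L], g$k),
               false_2 = err(g$label[1L], g$k2),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
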