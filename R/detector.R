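#' Classify magnitudes as low / high extremes
#'
#' A magnitude is low when strictly below `min_limit` and high when strictly
#' above `max_limit`; values on a boundary are neither. The two index lists are
#' disjoint whenever `min_limit <= max_limit`.
#'
#' @param magnitudes Numeric vector of magnitudes (m/s^2).
#' @param min_limit,max_limit Resolved numeric thresholds (m/s^2).
#' @return A list with integer index vectors `low` and `high` (1-based).
#' @export
classify_extremes <- function(magnitudes, min_limit, max_limit) {
  list(low = which(magnitudes < min_limit),
       high = which(magnitudes > max_limit))
}

.empty_sets <- function() {
  data.frame(kind = character(), set_id = integer(),
             first_index = integer(), last_index = integer(),
             first_entry = double(), last_entry = double(),
             n_members = integer(), stringsAsFactors = FALSE)
}

#' Cluster extreme indices into sets by entry gaps
#'
#' Partitions a sorted index list into maximal runs whose consecutive entry
#' gaps never exceed `sub_1`; a new set starts only where the gap is strictly
#' greater than `sub_1`. Each set is reported by its first and last member;
#' singleton sets are legal.
#'
#' @param indices Sorted integer sample indices (1-based).
#' @param entries Entry vector for the full series (see [compute_entries()]).
#' @param sub_1 Entry-gap threshold.
#' @param kind `"low"` or `"high"`, recorded in the output.
#' @return A data frame with one row per set: `kind`, `set_id`, `first_index`,
#'   `last_index`, `first_entry`, `last_entry`, `n_members`.
#' @export
cluster_extremes <- function(indices, entries, sub_1, kind = c("low", "high")) {
  kind <- match.arg(kind)
  if (length(indices) == 0L) return(.empty_sets())
  indices <- as.integer(indices)
  if (is.unsorted(indices, strictly = TRUE)) {
    stop("indices must be sorted strictly ascending", call. = FALSE)
  }
  e <- entries[indices]
  starts <- which(c(TRUE, diff(e) > sub_1))
  ends <- c(starts[-1L] - 1L, length(indices))
  data.frame(kind = kind,
             set_id = seq_along(starts),
             first_index = indices[starts],
             last_index = indices[ends],
             first_entry = e[starts],
             last_entry = e[ends],
             n_members = ends - starts + 1L,
             stringsAsFactors = FALSE)
}

.empty_candidates <- function() {
  data.frame(id = integer(), low_set = integer(), high_set = integer(),
             start_index = integer(), end_index = integer(),
             start_entry = double(), end_entry = double(), span = double(),
             peak_index = integer(), peak_magnitude = double(),
             status = character(), stringsAsFactors = FALSE)
}

.with_peaks <- function(cand, magnitudes) {
  if (nrow(cand) == 0L) return(cand)
  for (i in seq_len(nrow(cand))) {
    rng <- cand$start_index[i]:cand$end_index[i]
    p <- rng[which.max(magnitudes[rng])]
    cand$peak_index[i] <- p
    cand$peak_magnitude[i] <- magnitudes[p]
  }
  cand
}

#' Connect low sets to high sets into candidate falls
#'
#' Emits one candidate for every (low set L, high set H) pairing whose entry
#' span `H.last_entry - L.first_entry` is positive (the lows precede the highs)
#' and at most `fall_duration`. A candidate spans from the first member of its
#' low set to the last member of its high set; its peak is the largest
#' magnitude inside that span. A set may appear in several candidates; the
#' validator prunes the sharing later.
#'
#' @param low_sets,high_sets Set data frames from [cluster_extremes()].
#' @param fall_duration Maximum entry span of a possible fall.
#' @param magnitudes Optional magnitude vector; when supplied, peak index and
#'   peak magnitude are filled in.
#' @return A candidate data frame (possibly empty), ordered by
#'   `(start_entry, end_entry)`, with `status = "candidate"`.
#' @export
connect_candidates <- function(low_sets, high_sets, fall_duration,
                               magnitudes = NULL) {
  if (nrow(low_sets) == 0L || nrow(high_sets) == 0L) return(.empty_candidates())
  pairs <- expand.grid(li = seq_len(nrow(low_sets)),
                       hi = seq_len(nrow(high_sets)))
  span <- high_sets$last_entry[pairs$hi] - low_sets$first_entry[pairs$li]
  keep <- span > 0 & span <= fall_duration
  if (!any(keep)) return(.empty_candidates())
  pairs <- pairs[keep, , drop = FALSE]
  span <- span[keep]
  cand <- data.frame(
    id = 0L,
    low_set = low_sets$set_id[pairs$li],
    high_set = high_sets$set_id[pairs$hi],
    start_index = low_sets$first_index[pairs$li],
    end_index = high_sets$last_index[pairs$hi],
    start_entry = low_sets$first_entry[pairs$li],
    end_entry = high_sets$last_entry[pairs$hi],
    span = span,
    peak_index = NA_integer_,
    peak_magnitude = NA_real_,
    status = "candidate",
    stringsAsFactors = FALSE
  )
  cand <- cand[order(cand$start_entry, cand$end_entry), , drop = FALSE]
  cand$id <- seq_len(nrow(cand))
  rownames(cand) <- NULL
  if (!is.null(magnitudes)) cand <- .with_peaks(cand, magnitudes)
  cand
}

#' Stage one: detect candidate falls
#'
#' Composes the magnitude and entry computations, threshold resolution,
#' low/high classification, set clustering and candidate connection. Returns
#' an object carrying the full working state so the validator (and reports)
#' can reuse it.
#'
#' @param series An [accel_series()].
#' @param thresholds A [threshold_set()].
#' @return An object of class `fall_detection`: a list with `series`,
#'   `magnitudes`, `entries`, `thresholds` (resolved), `lows`, `highs`,
#'   `low_sets`, `high_sets`, `candidates`.
#' @examples
#' sc <- generate_scenario(fall_scenario(n_falls = 1, seed = 7, noise_sd = 0))
#' det <- detect_falls(sc$series)
#' nrow(det$candidates)
#' @export
detect_falls <- function(series, thresholds = threshold_set()) {
  ms <- magnitude_series(series)
  th <- resolve_thresholds(thresholds, ms$magnitudes)
  cls <- classify_extremes(ms$magnitudes, th$min_limit, th$max_limit)
  low_sets <- cluster_extremes(cls$low, ms$entries, th$sub_1, "low")
  high_sets <- cluster_extremes(cls$high, ms$entries, th$sub_1, "high")
  cand <- connect_candidates(low_sets, high_sets, th$fall_duration,
                             ms$magnitudes)
  structure(
    list(series = series, magnitudes = ms$magnitudes, entries = ms$entries,
         thresholds = th, lows = cls$low, highs = cls$high,
         low_sets = low_sets, high_sets = high_sets, candidates = cand),
    class = "fall_detection"
  )
}

#' @export
print.fall_detection <- function(x, ...) {
  cat(sprintf(
    "<fall_detection> %d samples | %d low sets, %d high sets | %d candidate fall(s)\n",
    length(x$magnitudes), nrow(x$low_sets), nrow(x$high_sets),
    nrow(x$candidates)))
  invisible(x)
}
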