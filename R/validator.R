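.is_rejected <- function(status) startsWith(status, "rejected")

#' Resolve extremes shared across candidate falls
#'
#' When several candidates share a low or high set only one may survive: the
#' one with the smallest entry span. Resolution is a global greedy pass —
#' repeatedly keep the shortest remaining candidate (ties broken by earlier
#' start, then id) and reject every candidate sharing one of its sets — which
#' is applied until no shared extremes remain. Survivors that outlived a
#' sharing rival are marked `kept-shorter`.
#'
#' @param candidates Candidate data frame from [connect_candidates()]. Rows
#'   already rejected are ignored.
#' @return The data frame with statuses updated: losers become
#'   `rejected-shared`; no rows are removed.
#' @export
resolve_shared_extremes <- function(candidates) {
  cand <- candidates
  act <- which(!.is_rejected(cand$status))
  if (length(act) <= 1L) return(cand)
  had_rival <- vapply(act, function(i) {
    any(act != i & (cand$low_set[act] == cand$low_set[i] |
                    cand$high_set[act] == cand$high_set[i]))
  }, logical(1))
  ord <- act[order(cand$span[act], cand$start_entry[act], cand$id[act])]
  used_low <- integer(0)
  used_high <- integer(0)
  for (i in ord) {
    if (cand$low_set[i] %in% used_low || cand$high_set[i] %in% used_high) {
      cand$status[i] <- "rejected-shared"
    } else {
      used_low <- c(used_low, cand$low_set[i])
      used_high <- c(used_high, cand$high_set[i])
    }
  }
  winners <- act[had_rival & !.is_rejected(cand$status[act])]
  cand$status[winners] <- "kept-shorter"
  cand
}

#' Shrink or reject over-long candidate falls
#'
#' A candidate is "long" when its entry span exceeds `fall_limitation`. If some
#' classified-low sample inside the fall brings the span within the limit, the
#' start is shifted to the qualifying low closest to the end (largest entry)
#' and the peak is recomputed over the shortened range (`status = "shrunk"`);
#' otherwise the candidate is rejected (`status = "rejected-long"`). Short
#' candidates pass unchanged.
#'
#' @param candidates Candidate data frame.
#' @param low_indices Integer indices of all classified-low samples.
#' @param entries Entry vector for the full series.
#' @param fall_limitation Entry-span threshold defining a long fall.
#' @param magnitudes Magnitude vector, used to recompute the peak after a
#'   shift.
#' @return The data frame with statuses, spans and start points updated.
#' @export
shrink_or_reject_long <- function(candidates, low_indices, entries,
                                  fall_limitation, magnitudes) {
  cand <- candidates
  for (i in seq_len(nrow(cand))) {
    if (.is_rejected(cand$status[i])) next
    if (cand$span[i] <= fall_limitation) next
    e_low <- entries[low_indices]
    ok <- e_low < cand$end_entry[i] &
      (cand$end_entry[i] - e_low) <= fall_limitation
    if (!any(ok)) {
      cand$status[i] <- "rejected-long"
      next
    }
    j <- low_indices[ok][which.max(e_low[ok])]
    cand$start_index[i] <- j
    cand$start_entry[i] <- entries[j]
    cand$span[i] <- cand$end_entry[i] - cand$start_entry[i]
    rng <- cand$start_index[i]:cand$end_index[i]
    p <- rng[which.max(magnitudes[rng])]
    cand$peak_index[i] <- p
    cand$peak_magnitude[i] <- magnitudes[p]
    cand$status[i] <- "shrunk"
  }
  cand
}

# Population-style sd with a length-1 window defined as 0; the stability check
# needs a finite value for any non-empty window.
.window_sd <- function(x) if (length(x) < 2L) 0 else stats::sd(x)

#' Final acceptance checks: post-fall stability or peak dominance
#'
#' A surviving candidate is accepted iff at least one assumption holds:
#' \describe{
#'   \item{A (stability)}{over the samples whose entries lie in
#'     `(end_entry, end_entry + stability_window]`, the mean magnitude is within
#'     `mean_tol` of g and the standard deviation is at most `std_tol` — the
#'     subject is on the ground and no longer moving. An empty window is
#'     insufficient evidence and fails A.}
#'   \item{B (peak dominance)}{the candidate's peak strictly exceeds every
#'     magnitude above `max_limit_2` whose entry lies within `dist_1` before
#'     the start or `dist_2` after the end (the fall's own span excluded).
#'     With no such neighbouring high, B holds vacuously.}
#' }
#'
#' @param candidates Candidate data frame (after sharing/length resolution).
#' @param magnitudes,entries Full-series vectors.
#' @param thresholds Resolved [threshold_set()].
#' @param g Gravity reference (m/s^2).
#' @return The data frame with `status` set to `accepted` or
#'   `rejected-checks`, and an `accepted_via` column (`"stability"`,
#'   `"peak"`, or `NA`).
#' @export
final_checks <- function(candidates, magnitudes, entries, thresholds,
                         g = standard_gravity) {
  cand <- candidates
  cand$accepted_via <- rep(NA_character_, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (.is_rejected(cand$status[i])) next
    s <- cand$start_entry[i]
    e <- cand$end_entry[i]
    win <- entries > e & entries <= e + thresholds$stability_window
    pass_a <- FALSE
    if (any(win)) {
      m <- magnitudes[win]
      pass_a <- abs(mean(m) - g) <= thresholds$mean_tol &&
        .window_sd(m) <= thresholds$std_tol
    }
    nb <- ((entries >= s - thresholds$dist_1 & entries < s) |
           (entries > e & entries <= e + thresholds$dist_2)) &
      magnitudes > thresholds$max_limit_2
    pass_b <- !any(nb) || cand$peak_magnitude[i] > max(magnitudes[nb])
    if (pass_a || pass_b) {
      cand$status[i] <- "accepted"
      cand$accepted_via[i] <- if (pass_a) "stability" else "peak"
    } else {
      cand$status[i] <- "rejected-checks"
    }
  }
  cand
}

# Safety net: accepted falls must be pairwise non-overlapping in entry span.
# Set-disjoint survivors can in rare geometries still overlap in time (the
# bridging candidate that would have linked them was consumed by an even
# shorter one); keep the shorter fall, tie to the earlier start.
.resolve_overlaps <- function(cand) {
  acc <- which(cand$status == "accepted")
  if (length(acc) <= 1L) return(cand)
  ord <- acc[order(cand$span[acc], cand$start_entry[acc], cand$id[acc])]
  kept <- integer(0)
  for (i in ord) {
    clash <- any(cand$start_entry[kept] < cand$end_entry[i] &
                 cand$start_entry[i] < cand$end_entry[kept])
    if (clash) {
      cand$status[i] <- "rejected-overlap"
      cand$accepted_via[i] <- NA_character_
    } else {
      kept <- c(kept, i)
    }
  }
  cand
}

.check_label <- function(status, via) {
  switch(status,
         "rejected-shared" = "shared-extreme",
         "kept-shorter" = "shared-extreme",
         "shrunk" = "long-shrunk",
         "rejected-long" = "long-rejected",
         "accepted" = if (identical(via, "stability")) "stability-pass"
                      else if (identical(via, "peak")) "peak-pass"
                      else "checks-disabled",
         "rejected-checks" = "rejected-checks",
         "rejected-overlap" = "overlap",
         status)
}

.stage_transitions <- function(before, after) {
  ch <- which(after$status != before$status[match(after$id, before$id)])
  if (!length(ch)) {
    return(data.frame(id = integer(), check = character(), from = character(),
                      to = character(), stringsAsFactors = FALSE))
  }
  via <- if ("accepted_via" %in% names(after)) after$accepted_via[ch]
         else rep(NA_character_, length(ch))
  data.frame(
    id = after$id[ch],
    check = mapply(.check_label, after$status[ch], via, USE.NAMES = FALSE),
    from = before$status[match(after$id[ch], before$id)],
    to = after$status[ch],
    stringsAsFactors = FALSE
  )
}

#' Stage two: validate candidate falls
#'
#' Runs the three validation stages — shared-extreme resolution, long-fall
#' shrink/reject, and the two final acceptance assumptions — over the
#' candidates of a [detect_falls()] result, then resolves any residual time
#' overlap among accepted falls. With `apply_final_checks = FALSE` the last
#' stage is skipped and every candidate surviving the first two stages is
#' accepted (useful for quantifying how much the final checks contribute).
#'
#' @param detection A `fall_detection` object from [detect_falls()].
#' @param apply_final_checks Logical; skip the final assumptions when `FALSE`.
#' @return An object of class `fall_report`: a list with
#'   \describe{
#'     \item{accepted}{data frame of accepted falls (`start_time`/`end_time`
#'       in seconds, entries, peak magnitude, `accepted_via`), ordered by
#'       start time;}
#'     \item{candidates}{all candidates with their final status;}
#'     \item{transitions}{per-candidate trail of status changes with the check
#'       that caused each;}
#'     \item{no_fall}{`TRUE` when nothing was accepted;}
#'     \item{thresholds}{the resolved thresholds used.}
#'   }
#' @export
validate_falls <- function(detection, apply_final_checks = TRUE) {
  stopifnot(inherits(detection, "fall_detection"))
  th <- detection$thresholds
  c0 <- detection$candidates
  c1 <- resolve_shared_extremes(c0)
  c2 <- shrink_or_reject_long(c1, detection$lows, detection$entries,
                              th$fall_limitation, detection$magnitudes)
  if (apply_final_checks) {
    c3 <- final_checks(c2, detection$magnitudes, detection$entries, th)
  } else {
    c3 <- c2
    c3$accepted_via <- rep(NA_character_, nrow(c3))
    live <- !.is_rejected(c3$status)
    c3$status[live] <- "accepted"
  }
  c4 <- .resolve_overlaps(c3)
  transitions <- rbind(.stage_transitions(c0, c1),
                       .stage_transitions(c1, c2),
                       .stage_transitions(c2, c3),
                       .stage_transitions(c3, c4))
  acc <- c4[c4$status == "accepted", , drop = FALSE]
  ts <- detection$series$timestamps
  accepted <- data.frame(
    id = acc$id,
    start_index = acc$start_index, end_index = acc$end_index,
    start_time = ts[acc$start_index], end_time = ts[acc$end_index],
    start_entry = acc$start_entry, end_entry = acc$end_entry,
    span = acc$span,
    peak_index = acc$peak_index, peak_magnitude = acc$peak_magnitude,
    accepted_via = acc$accepted_via,
    stringsAsFactors = FALSE
  )
  accepted <- accepted[order(accepted$start_time), , drop = FALSE]
  rownames(accepted) <- NULL
  structure(
    list(accepted = accepted, candidates = c4, transitions = transitions,
         no_fall = nrow(accepted) == 0L, thresholds = th),
    class = "fall_report"
  )
}

#' @export
print.fall_report <- function(x, ...) {
  if (x$no_fall) {
    cat("<fall_report> No Fall (", nrow(x$candidates), " candidate(s) examined)\n",
        sep = "")
  } else {
    cat(sprintf("<fall_report> %d accepted fall(s) out of %d candidate(s)\n",
                nrow(x$accepted), nrow(x$candidates)))
    print(x$accepted[, c("start_time", "end_time", "peak_magnitude",
                         "accepted_via")], digits = 4)
  }
  invisible(x)
}

#' Full pipeline: detect then validate
#'
#' @param series An [accel_series()].
#' @param thresholds A [threshold_set()].
#' @param apply_final_checks Passed to [validate_falls()].
#' @return A `fall_report` (see [validate_falls()]).
#' @examples
#' sc <- generate_scenario(fall_scenario(n_falls = 2, seed = 3))
#' find_falls(sc$series)
#' @export
find_falls <- function(series, thresholds = threshold_set(),
                       apply_final_checks = TRUE) {
  validate_falls(detect_falls(series, thresholds), apply_final_checks)
}
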