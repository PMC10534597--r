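# Build an accel_series whose magnitude trace equals `m` exactly (all on x).
series_from_magnitudes <- function(m, f = 100, t = NULL) {
  accel_series(x = m, y = rep(0, length(m)), z = rep(0, length(m)),
               timestamps = t, frequency_hz = f)
}

# Hand-crafted canonical fall at 100 Hz: 1 s rest at g, 0.2 s dip at 3 m/s^2,
# 0.3 s back at g, a single 40 m/s^2 impact sample, then 2 s rest at g.
# With defaults the resolved max_limit is 30, so 3 < 6.5 < 30 < 40.
canonical_fall_magnitudes <- function() {
  c(rep(standard_gravity, 100),  # 0.00-0.99 s rest
    rep(3, 20),                  # 1.00-1.19 s dip (lows)
    rep(standard_gravity, 30),   # 1.20-1.49 s between
    40,                          # 1.50 s impact (high)
    rep(standard_gravity, 200))  # settling
}

canonical_dip_range <- c(101L, 120L)
canonical_spike_index <- 151L

# Candidate data frame row(s) in the detector's layout, for validator units.
make_candidates <- function(...) {
  rows <- data.frame(..., stringsAsFactors = FALSE)
  defaults <- list(peak_index = NA_integer_, peak_magnitude = NA_real_,
                   status = "candidate")
  for (nm in names(defaults)) {
    if (is.null(rows[[nm]])) rows[[nm]] <- rep(defaults[[nm]], nrow(rows))
  }
  if (is.null(rows$span)) rows$span <- rows$end_entry - rows$start_entry
  if (is.null(rows$id)) rows$id <- seq_len(nrow(rows))
  rows
}

# Rebuild a detection whose candidate list is exactly the accepted falls of a
# report (statuses reset), to probe validator idempotence.
detection_from_accepted <- function(detection, report) {
  acc <- report$accepted
  det <- detection
  det$candidates <- data.frame(
    id = seq_len(nrow(acc)),
    low_set = seq_len(nrow(acc)),
    high_set = seq_len(nrow(acc)),
    start_index = acc$start_index, end_index = acc$end_index,
    start_entry = acc$start_entry, end_entry = acc$end_entry,
    span = acc$span,
    peak_index = acc$peak_index, peak_magnitude = acc$peak_magnitude,
    status = "candidate", stringsAsFactors = FALSE)
  det
}

# A detection counts as recovering a ground-truth fall when some accepted
# fall shares at least one sample with the truth interval.
events_recovered <- function(report, truth) {
  truth <- truth[truth$label == "fall", , drop = FALSE]
  if (nrow(truth) == 0L) return(integer(0))
  acc <- report$accepted
  hit <- vapply(seq_len(nrow(truth)), function(i) {
    any(acc$start_index <= truth$end_index[i] &
        truth$start_index[i] <= acc$end_index)
  }, logical(1))
  which(hit)
}
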