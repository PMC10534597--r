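`%||%` <- function(a, b) if (is.null(a)) b else a

.event_kinds <- c("fall", "rest", "walk", "jog", "jump", "sit")
.default_event_duration <- c(fall = 2.8, rest = 2, walk = 5, jog = 5,
                             jump = 1.5, sit = 2)

#' Scenario specification for the synthetic trace generator
#'
#' Describes a seeded, fully reproducible tri-axial accelerometer recording:
#' a rest baseline at gravity plus a list of non-overlapping events. Event
#' kinds: `fall` (magnitude dip, then a spike shortly after, then settling at
#' g), `walk`/`jog` (sinusoidal oscillation inside the low/high limits),
#' `jump` (a spike with a smaller earlier peak but no qualifying dip), `sit`
#' (a shallow dip and mild bump), `rest` (nothing beyond the baseline).
#'
#' @param duration_s Total duration in seconds.
#' @param events Data frame with columns `kind`, `start_s` and optionally
#'   `duration_s` (per-kind default used when `NA`), or `NULL` for pure rest.
#' @param frequency_hz Sampling rate in Hz.
#' @param noise_sd Gaussian noise on the magnitude (m/s^2) before axis
#'   decomposition; capped at 0.3 in post-impact settling windows.
#' @param seed Integer seed; fully determines the output.
#' @return An object of class `scenario_spec`.
#' @seealso [generate_scenario()], [fall_scenario()], [adl_scenario()]
#' @export
scenario_spec <- function(duration_s, events = NULL, frequency_hz = 100,
                          noise_sd = 0.2, seed = 1L) {
  stopifnot(is.numeric(duration_s), duration_s > 0,
            is.numeric(frequency_hz), frequency_hz > 0,
            is.numeric(noise_sd), noise_sd >= 0)
  if (is.null(events)) {
    events <- data.frame(kind = character(), start_s = double(),
                         duration_s = double(), stringsAsFactors = FALSE)
  }
  if (!all(c("kind", "start_s") %in% names(events))) {
    stop("events must have columns kind and start_s", call. = FALSE)
  }
  if (!all(events$kind %in% .event_kinds)) {
    stop("unknown event kind; known kinds: ",
         paste(.event_kinds, collapse = ", "), call. = FALSE)
  }
  if (is.null(events$duration_s)) events$duration_s <- NA_real_
  events$duration_s <- ifelse(is.na(events$duration_s),
                              .default_event_duration[events$kind],
                              events$duration_s)
  events <- events[order(events$start_s), , drop = FALSE]
  rownames(events) <- NULL
  ends <- events$start_s + events$duration_s
  if (any(events$start_s < 0) || any(ends > duration_s + 1e-9)) {
    stop("events must lie within [0, duration_s]", call. = FALSE)
  }
  if (nrow(events) > 1L &&
      any(events$start_s[-1L] < ends[-nrow(events)] - 1e-9)) {
    stop("events must not overlap in time", call. = FALSE)
  }
  structure(
    list(duration_s = duration_s, events = events,
         frequency_hz = frequency_hz, noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "scenario_spec"
  )
}

# Run expr with a private RNG stream; the caller's .Random.seed is untouched.
.with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(expr)
}

#' Generate a synthetic accelerometer scenario
#'
#' Scripts a per-sample magnitude profile from the scenario's events, adds
#' Gaussian magnitude noise, and decomposes each magnitude onto x/y/z along a
#' random unit vector (so the scripted magnitude is preserved exactly).
#' Fall morphology: a dip uniform in \[1, 5.5\] m/s^2 lasting 0.1–0.3 s, a
#' spike in \[35, 60\] m/s^2 of 1–3 samples within 0.8 s of the dip, then at
#' least 1.5 s of settling at g with noise capped at 0.3 m/s^2.
#'
#' @param spec A [scenario_spec()].
#' @return An object of class `accel_scenario`: a list with `series` (an
#'   [accel_series()]), `truth` (data frame of ground-truth event intervals
#'   with `start_index`, `end_index`, `start_s`, `end_s`, `kind`, `label`),
#'   and `spec`.
#' @examples
#' sc <- generate_scenario(fall_scenario(n_falls = 1, seed = 42))
#' sc$truth
#' @export
generate_scenario <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  .with_seed(spec$seed, {
    f <- spec$frequency_hz
    n <- max(1L, as.integer(round(spec$duration_s * f)))
    t <- (seq_len(n) - 1) / f
    mag <- rep(standard_gravity, n)
    sd_vec <- rep(spec$noise_sd, n)
    truth <- list()
    span_idx <- function(from, to) which(t >= from & t < to)

    for (i in seq_len(nrow(spec$events))) {
      kind <- spec$events$kind[i]
      s <- spec$events$start_s[i]
      d <- spec$events$duration_s[i]
      idx <- span_idx(s, s + d)
      if (!length(idx)) next
      tt <- t[idx] - s
      first <- idx[1L]; last <- idx[length(idx)]
      if (kind == "fall") {
        dip_dur <- runif(1, 0.1, 0.3)
        dip_mag <- runif(1, 1, 5.5)
        gap <- runif(1, 0.15, 0.6)
        n_spike <- sample(1:3, 1)
        spike_mag <- runif(1, 35, 60)
        dip_idx <- span_idx(s, s + dip_dur)
        spike_start <- which(t >= s + dip_dur + gap)[1L]
        spike_idx <- spike_start:min(spike_start + n_spike - 1L, n)
        mag[dip_idx] <- dip_mag
        mag[spike_idx] <- spike_mag
        settle <- span_idx(t[spike_idx[length(spike_idx)]] + 1 / f,
                           t[spike_idx[length(spike_idx)]] + 1.5)
        sd_vec[settle] <- min(spec$noise_sd, 0.3)
        first <- dip_idx[1L]; last <- spike_idx[length(spike_idx)]
      } else if (kind == "walk") {
        amp <- runif(1, 1.5, 2.5)
        mag[idx] <- standard_gravity + amp * sin(2 * pi * 1.8 * tt)
      } else if (kind == "jog") {
        amp <- runif(1, 2.5, 3.1)
        mag[idx] <- standard_gravity + amp * sin(2 * pi * 2.8 * tt)
      } else if (kind == "jump") {
        pre_idx <- span_idx(s, s + 0.04)
        mag[pre_idx] <- runif(1, 16, 24)
        main_start <- which(t >= s + 0.35)[1L]
        main_idx <- main_start:min(main_start + sample(1:2, 1) - 1L, n)
        mag[main_idx] <- runif(1, 35, 50)
      } else if (kind == "sit") {
        dip_idx <- span_idx(s, s + 0.3)
        mag[dip_idx] <- runif(1, 7.2, 8.5)
        bump_start <- which(t >= s + 0.4)[1L]
        bump_idx <- bump_start:min(bump_start + 1L, n)
        mag[bump_idx] <- runif(1, 14, 18)
      }
      truth[[length(truth) + 1L]] <- data.frame(
        start_index = first, end_index = last,
        start_s = t[first], end_s = t[last],
        kind = kind,
        label = if (kind == "fall") "fall" else "non-fall",
        stringsAsFactors = FALSE)
    }

    if (spec$noise_sd > 0) mag <- pmax(mag + rnorm(n, 0, sd_vec), 0.01)

    v <- matrix(rnorm(3L * n), ncol = 3L)
    nv <- sqrt(rowSums(v^2))
    zero <- nv < 1e-12
    if (any(zero)) { v[zero, ] <- rep(c(0, 0, 1), each = sum(zero)); nv[zero] <- 1 }
    x <- mag * v[, 1L] / nv
    y <- mag * v[, 2L] / nv
    z <- mag * v[, 3L] / nv

    truth <- if (length(truth)) do.call(rbind, truth) else
      data.frame(start_index = integer(), end_index = integer(),
                 start_s = double(), end_s = double(),
                 kind = character(), label = character(),
                 stringsAsFactors = FALSE)
    label <- if (any(truth$label == "fall")) "fall" else "non-fall"
    structure(
      list(series = accel_series(x, y, z, timestamps = t,
                                 frequency_hz = f, label = label),
           truth = truth, spec = spec),
      class = "accel_scenario"
    )
  })
}

#' @export
print.accel_scenario <- function(x, ...) {
  cat(sprintf("<accel_scenario> seed %d, %d samples, %d event(s): %s\n",
              x$spec$seed, n_samples(x$series), nrow(x$truth),
              if (nrow(x$truth)) paste(x$truth$kind, collapse = ", ") else "rest"))
  invisible(x)
}

#' Convenience scenario builders
#'
#' `fall_scenario()` places `n_falls` fall events separated by more than 3 s
#' of rest; `adl_scenario()` builds a single daily-activity confounder trace
#' (or pure rest).
#'
#' @param n_falls Number of fall events.
#' @param seed,noise_sd,frequency_hz Passed to [scenario_spec()].
#' @param lead_s Rest before the first event (seconds).
#' @param period_s Start-to-start spacing between falls (seconds).
#' @return A [scenario_spec()].
#' @export
fall_scenario <- function(n_falls = 1, seed = 1L, noise_sd = 0.2,
                          frequency_hz = 100, lead_s = 2, period_s = 6) {
  events <- data.frame(kind = "fall",
                       start_s = lead_s + (seq_len(n_falls) - 1) * period_s,
                       stringsAsFactors = FALSE)
  scenario_spec(duration_s = lead_s + n_falls * period_s, events = events,
                frequency_hz = frequency_hz, noise_sd = noise_sd, seed = seed)
}

#' @rdname fall_scenario
#' @param kind Activity kind for `adl_scenario()`.
#' @param duration_s Total duration of the activity trace (seconds).
#' @export
adl_scenario <- function(kind = c("rest", "walk", "jog", "jump", "sit"),
                         seed = 1L, noise_sd = 0.2, frequency_hz = 100,
                         duration_s = 8) {
  kind <- match.arg(kind)
  events <- if (kind == "rest") NULL else
    data.frame(kind = kind, start_s = 1.5,
               duration_s = min(.default_event_duration[[kind]],
                                duration_s - 2),
               stringsAsFactors = FALSE)
  scenario_spec(duration_s = duration_s, events = events,
                frequency_hz = frequency_hz, noise_sd = noise_sd, seed = seed)
}

#' Seeded synthetic benchmark of labeled trials
#'
#' Builds `n_fall` single-fall trials and `n_adl` daily-activity trials
#' (cycling rest, walk, jog, jump, sit), each from its own derived seed, as a
#' list of [fall_trial()] objects ready for [score_trial()] accounting.
#'
#' @param n_fall,n_adl Trial counts per class.
#' @param seed Master seed; per-trial seeds are derived deterministically.
#' @param noise_sd Magnitude noise (m/s^2).
#' @return A list of `fall_trial` objects.
#' @export
synthetic_benchmark <- function(n_fall = 30, n_adl = 30, seed = 1L,
                                noise_sd = 0.2) {
  seed <- as.integer(seed)
  derive <- function(i) as.integer((abs(seed) + 104729L * i) %% 2147483562L) + 1L
  adl_kinds <- c("rest", "walk", "jog", "jump", "sit")
  trials <- vector("list", n_fall + n_adl)
  for (i in seq_len(n_fall)) {
    sc <- generate_scenario(fall_scenario(n_falls = 1, seed = derive(i),
                                          noise_sd = noise_sd))
    trials[[i]] <- fall_trial(sc$series, label = "fall", sub_class = "fall",
                              dataset_id = "synthetic",
                              trial_id = sprintf("fall-%03d", i))
  }
  for (j in seq_len(n_adl)) {
    kind <- adl_kinds[(j - 1L) %% length(adl_kinds) + 1L]
    sc <- generate_scenario(adl_scenario(kind, seed = derive(n_fall + j),
                                         noise_sd = noise_sd))
    trials[[n_fall + j]] <- fall_trial(sc$series, label = "non-fall",
                                       sub_class = kind,
                                       dataset_id = "synthetic",
                                       trial_id = sprintf("adl-%03d", j))
  }
  trials
}
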