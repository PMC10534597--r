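# Independent brute-force reference implementations, written as plain loops
# straight from the rules, against which the vectorized pipeline is checked.

oracle_entries <- function(timestamps, frequency_hz) {
  e <- numeric(length(timestamps))
  e[1] <- 0
  for (i in seq_along(timestamps)[-1]) {
    e[i] <- (timestamps[i] - timestamps[i - 1]) / 10 + e[i - 1] +
      100 / frequency_hz
  }
  e
}

oracle_classify <- function(m, min_limit, max_limit) {
  low <- integer(0); high <- integer(0)
  for (i in seq_along(m)) {
    if (m[i] < min_limit) low <- c(low, i)
    else if (m[i] > max_limit) high <- c(high, i)
  }
  list(low = low, high = high)
}

# Sets as a list of member-index vectors.
oracle_cluster <- function(indices, entries, sub_1) {
  sets <- list()
  cur <- integer(0)
  for (i in indices) {
    if (length(cur) && entries[i] - entries[cur[length(cur)]] > sub_1) {
      sets[[length(sets) + 1]] <- cur
      cur <- integer(0)
    }
    cur <- c(cur, i)
  }
  if (length(cur)) sets[[length(sets) + 1]] <- cur
  sets
}

oracle_connect <- function(low_sets, high_sets, entries, fall_duration) {
  out <- list()
  for (li in seq_along(low_sets)) {
    for (hi in seq_along(high_sets)) {
      s <- low_sets[[li]][1]
      e <- high_sets[[hi]][length(high_sets[[hi]])]
      span <- entries[e] - entries[s]
      if (span > 0 && span <= fall_duration) {
        out[[length(out) + 1]] <- data.frame(
          low_set = li, high_set = hi,
          start_index = s, end_index = e,
          start_entry = entries[s], end_entry = entries[e], span = span)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(low_set = integer(), high_set = integer(),
                      start_index = integer(), end_index = integer(),
                      start_entry = double(), end_entry = double(),
                      span = double()))
  }
  do.call(rbind, out)
}

oracle_detect <- function(m, entries, th) {
  cls <- oracle_classify(m, th$min_limit, th$max_limit)
  lows <- oracle_cluster(cls$low, entries, th$sub_1)
  highs <- oracle_cluster(cls$high, entries, th$sub_1)
  list(cand = oracle_connect(lows, highs, entries, th$fall_duration),
       low_indices = cls$low)
}

# Three validation rules plus the final overlap resolution, as explicit loops.
oracle_validate <- function(m, entries, th, g = standard_gravity) {
  det <- oracle_detect(m, entries, th)
  cand <- det$cand
  if (nrow(cand) == 0L) return(cand)
  cand <- cand[order(cand$start_entry, cand$end_entry), , drop = FALSE]
  cand$id <- seq_len(nrow(cand))

  # 1. shared extremes: repeatedly keep the globally shortest, drop sharers
  pool <- cand
  surv <- cand[0, , drop = FALSE]
  while (nrow(pool)) {
    o <- order(pool$span, pool$start_entry, pool$id)
    best <- pool[o[1], , drop = FALSE]
    surv <- rbind(surv, best)
    pool <- pool[!(pool$low_set == best$low_set |
                   pool$high_set == best$high_set), , drop = FALSE]
  }

  # 2. shrink or reject long falls
  kept <- surv[0, , drop = FALSE]
  for (i in seq_len(nrow(surv))) {
    row <- surv[i, , drop = FALSE]
    if (row$span > th$fall_limitation) {
      best_low <- NA_integer_
      for (j in det$low_indices) {
        if (entries[j] < row$end_entry &&
            row$end_entry - entries[j] <= th$fall_limitation) {
          if (is.na(best_low) || entries[j] > entries[best_low]) best_low <- j
        }
      }
      if (is.na(best_low)) next
      row$start_index <- best_low
      row$start_entry <- entries[best_low]
      row$span <- row$end_entry - row$start_entry
    }
    kept <- rbind(kept, row)
  }

  # 3. final checks: post-fall stability near g OR peak dominance
  acc <- kept[0, , drop = FALSE]
  for (i in seq_len(nrow(kept))) {
    row <- kept[i, , drop = FALSE]
    rng <- row$start_index:row$end_index
    peak <- max(m[rng])
    win <- which(entries > row$end_entry &
                 entries <= row$end_entry + th$stability_window)
    pass_a <- FALSE
    if (length(win)) {
      mw <- m[win]
      sdw <- if (length(mw) < 2) 0 else sd(mw)
      pass_a <- abs(mean(mw) - g) <= th$mean_tol && sdw <= th$std_tol
    }
    nb <- which(((entries >= row$start_entry - th$dist_1 &
                  entries < row$start_entry) |
                 (entries > row$end_entry &
                  entries <= row$end_entry + th$dist_2)) &
                m > th$max_limit_2)
    pass_b <- length(nb) == 0 || all(peak > m[nb])
    if (pass_a || pass_b) acc <- rbind(acc, row)
  }

  # 4. overlap resolution among accepted (shorter wins, tie earlier start)
  final <- acc[0, , drop = FALSE]
  o <- order(acc$span, acc$start_entry, acc$id)
  for (i in o) {
    row <- acc[i, , drop = FALSE]
    clash <- FALSE
    for (k in seq_len(nrow(final))) {
      if (final$start_entry[k] < row$end_entry &&
          row$start_entry < final$end_entry[k]) clash <- TRUE
    }
    if (!clash) final <- rbind(final, row)
  }
  final[order(final$start_entry), , drop = FALSE]
}

# Random instance shared by the equivalence tests: a magnitude trace with
# injected dips/spikes plus a random (numeric-rule) threshold set.
random_case <- function(seed) {
  set.seed(seed)
  n <- sample(5:400, 1)
  f <- sample(c(20, 50, 60, 100, 200), 1)
  t <- (seq_len(n) - 1) / f
  if (runif(1) < 0.3 && n > 1) {
    t <- t + c(0, cumsum(runif(n - 1, 0, 0.3 / f)))  # timing jitter
  }
  m <- runif(n, 8, 25)
  for (k in seq_len(sample(0:6, 1))) {
    at <- sample(n, 1)
    len <- sample(1:10, 1)
    rng <- at:min(at + len - 1, n)
    if (runif(1) < 0.5) m[rng] <- runif(1, 0.5, 6) else m[rng] <- runif(1, 30, 60)
  }
  fd <- runif(1, 60, 150)
  th <- threshold_set(
    min_limit = runif(1, 3, 8),
    max_limit = runif(1, 26, 45),
    sub_1 = runif(1, 20, 80),
    fall_duration = fd,
    fall_limitation = runif(1, 40, fd),
    dist_1 = runif(1, 50, 150),
    dist_2 = runif(1, 50, 150),
    max_limit_2 = runif(1, 26, 50),
    mean_tol = runif(1, 0.5, 3),
    std_tol = runif(1, 0.5, 3))
  list(series = series_from_magnitudes(m, f = f, t = t), m = m, t = t, th = th)
}

expect_matches_oracle <- function(case) {
  det <- detect_falls(case$series, case$th)
  th_res <- det$thresholds
  ora <- oracle_detect(case$m, det$entries, th_res)
  key <- function(d) {
    if (nrow(d) == 0L) return(character(0))
    sort(sprintf("%d:%d", d$start_index, d$end_index))
  }
  expect_identical(key(det$candidates), key(ora$cand))

  rep <- validate_falls(det)
  ova <- oracle_validate(case$m, det$entries, th_res)
  expect_identical(key(rep$accepted), key(ova))
  invisible(TRUE)
}
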