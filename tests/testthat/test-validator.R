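test_that("shared extremes keep the shorter fall", {
  cand <- make_candidates(
    low_set = c(1L, 2L), high_set = c(1L, 1L),
    start_index = c(10L, 60L), end_index = c(100L, 100L),
    start_entry = c(10, 60), end_entry = c(100, 100))
  out <- resolve_shared_extremes(cand)
  expect_equal(out$status, c("rejected-shared", "kept-shorter"))

  # disjoint candidates pass untouched
  disj <- make_candidates(
    low_set = c(1L, 2L), high_set = c(1L, 2L),
    start_index = c(10L, 300L), end_index = c(50L, 340L),
    start_entry = c(10, 300), end_entry = c(50, 340))
  expect_equal(resolve_shared_extremes(disj)$status, rep("candidate", 2))

  # equal spans: the earlier-starting candidate survives
  tie <- make_candidates(
    low_set = c(1L, 2L), high_set = c(1L, 1L),
    start_index = c(10L, 20L), end_index = c(50L, 60L),
    start_entry = c(10, 20), end_entry = c(50, 60))
  out_tie <- resolve_shared_extremes(tie)
  expect_equal(out_tie$status, c("kept-shorter", "rejected-shared"))
})

test_that("long falls are shrunk to the low nearest the impact, or rejected", {
  # entries are 1 unit apart; lows at entries 4, 34 and 89; end at entry 99
  entries <- 0:120
  m <- rep(standard_gravity, 121); m[100] <- 40
  low_indices <- c(5L, 35L, 90L)  # 1-based indices -> entries 4, 34, 89
  cand <- make_candidates(low_set = 1L, high_set = 1L,
                          start_index = 5L, end_index = 100L,
                          start_entry = 4, end_entry = 99)
  out <- shrink_or_reject_long(cand, low_indices, entries,
                               fall_limitation = 85, magnitudes = m)
  expect_equal(out$status, "shrunk")
  expect_equal(out$start_entry, 89)   # qualifying low closest to the end
  expect_equal(out$span, 10)
  expect_equal(out$peak_magnitude, 40)

  # with only the mid-range low available, the shift lands there instead
  out_mid <- shrink_or_reject_long(cand, c(5L, 35L), entries, 85, m)
  expect_equal(out_mid$start_entry, 34)
  expect_equal(out_mid$span, 65)

  # short candidates pass unchanged
  short <- make_candidates(low_set = 1L, high_set = 1L,
                           start_index = 60L, end_index = 100L,
                           start_entry = 59, end_entry = 99)
  expect_equal(shrink_or_reject_long(short, low_indices, entries, 85, m)$status,
               "candidate")

  # no qualifying low at all -> rejected as long
  out2 <- shrink_or_reject_long(cand, c(5L), entries, 85, m)
  expect_equal(out2$status, "rejected-long")
})

test_that("final checks accept via post-fall stability or peak dominance", {
  th <- resolve_thresholds(threshold_set(max_limit = 30), rep(10, 5))
  entries <- 0:400

  # A: settles at g after the fall, although an earlier neighbour dominates
  m_a <- rep(standard_gravity, 401)
  m_a[90] <- 40; m_a[31] <- 50  # fall peak 40, neighbour 50 within dist_1 before
  cand_a <- make_candidates(low_set = 1L, high_set = 1L,
                            start_index = 70L, end_index = 95L,
                            start_entry = 69, end_entry = 94,
                            peak_index = 90L, peak_magnitude = 40)
  out_a <- final_checks(cand_a, m_a, entries, th)
  expect_equal(out_a$status, "accepted")
  expect_equal(out_a$accepted_via, "stability")

  # B: post-fall window oscillates far from g, but the peak dominates
  m_b <- rep(standard_gravity, 401)
  m_b[90] <- 40
  m_b[96:200] <- standard_gravity + rep(c(5, -5), length.out = 105)
  cand_b <- make_candidates(low_set = 1L, high_set = 1L,
                            start_index = 70L, end_index = 95L,
                            start_entry = 69, end_entry = 94,
                            peak_index = 90L, peak_magnitude = 40)
  out_b <- final_checks(cand_b, m_b, entries, th)
  expect_equal(out_b$status, "accepted")
  expect_equal(out_b$accepted_via, "peak")

  # neither: dominated peak and unstable aftermath -> rejected
  m_c <- m_b; m_c[150] <- 50
  out_c <- final_checks(cand_b, m_c, entries, th)
  expect_equal(out_c$status, "rejected-checks")

  # an equal neighbouring peak defeats peak dominance (strict >)
  m_d <- m_b; m_d[150] <- 40
  expect_equal(final_checks(cand_b, m_d, entries, th)$status, "rejected-checks")

  # candidate at the very end: empty stability window fails A, B may accept
  m_e <- rep(standard_gravity, 96); m_e[90] <- 40
  cand_e <- make_candidates(low_set = 1L, high_set = 1L,
                            start_index = 70L, end_index = 96L,
                            start_entry = 69, end_entry = 95,
                            peak_index = 90L, peak_magnitude = 40)
  out_e <- final_checks(cand_e, m_e, entries[1:96], th)
  expect_equal(out_e$status, "accepted")
  expect_equal(out_e$accepted_via, "peak")
})

test_that("a canonical fall is accepted covering the dip-to-impact interval", {
  s <- series_from_magnitudes(canonical_fall_magnitudes())
  rep <- find_falls(s)
  expect_equal(nrow(rep$accepted), 1)
  expect_equal(rep$accepted$start_index, canonical_dip_range[1])
  expect_equal(rep$accepted$end_index, canonical_spike_index)
  expect_equal(rep$accepted$start_time, 1.00)
  expect_equal(rep$accepted$end_time, 1.50)
})

test_that("two dips sharing one spike yield a single accepted fall, the shorter pairing", {
  m <- rep(standard_gravity, 400)
  m[101:110] <- 3    # first dip at ~1.0 s
  m[166:170] <- 3    # second dip at ~1.65 s (> sub_1 entries past the first)
  m[181] <- 40       # one impact at 1.8 s
  rep <- find_falls(series_from_magnitudes(m))
  expect_equal(nrow(rep$accepted), 1)
  expect_equal(rep$accepted$start_index, 166)  # shorter pairing wins
  expect_true(any(rep$transitions$check == "shared-extreme"))
})

test_that("validation is idempotent and never creates a fall", {
  sc <- generate_scenario(fall_scenario(n_falls = 3, seed = 31))
  det <- detect_falls(sc$series)
  rep1 <- validate_falls(det)
  expect_true(all(rep1$accepted$id %in% det$candidates$id))  # conservation
  rep2 <- validate_falls(detection_from_accepted(det, rep1))
  cols <- c("start_index", "end_index", "start_entry", "end_entry")
  expect_equal(rep2$accepted[cols], rep1$accepted[cols])
})

test_that("accepted falls never overlap in entry span", {
  for (seed in c(101:130)) {
    case <- random_case(seed)
    rep <- find_falls(case$series, case$th)
    acc <- rep$accepted
    if (nrow(acc) > 1) {
      o <- order(acc$start_entry)
      expect_true(all(acc$start_entry[o][-1] >= acc$end_entry[o][-nrow(acc)]))
    }
    expect_true(all(rep$accepted$id %in% detect_falls(case$series, case$th)$candidates$id))
  }
})

test_that("acceptance tightens monotonically with the check tolerances", {
  sc <- generate_scenario(fall_scenario(n_falls = 5, seed = 37))
  n_acc <- function(mean_tol, std_tol, max_limit_2 = "max_limit") {
    nrow(find_falls(sc$series,
                    threshold_set(mean_tol = mean_tol, std_tol = std_tol,
                                  max_limit_2 = max_limit_2))$accepted)
  }
  base <- n_acc(1.5, 2.0)
  expect_lte(n_acc(0.5, 0.5), base)    # tighter stability -> fewer or equal
  expect_gte(n_acc(5, 5), base)        # looser -> more or equal
})
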