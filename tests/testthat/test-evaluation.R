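test_that("per-trial scoring applies the multiple-detection rule", {
  expect_equal(unclass(score_trial("fall", 2)),
               list(tp = 1, fp = 1, tn = 0, fn = 0))
  expect_equal(unclass(score_trial("fall", 0)),
               list(tp = 0, fp = 0, tn = 0, fn = 1))
  expect_equal(unclass(score_trial("non-fall", 0)),
               list(tp = 0, fp = 0, tn = 1, fn = 0))
  expect_equal(unclass(score_trial("non-fall", 3)),
               list(tp = 0, fp = 3, tn = 0, fn = 0))
  expect_error(score_trial("fall", -1), "non-negative")
})

test_that("metrics are the four quotients, NA on empty denominators", {
  m <- compute_metrics(confusion_counts(tp = 95, fp = 5, tn = 0, fn = 0))
  expect_equal(m$accuracy, 0.95)
  expect_equal(m$sensitivity, 1)
  expect_equal(m$specificity, 0)
  m2 <- compute_metrics(confusion_counts(tp = 9, fp = 1, tn = 0, fn = 0))
  expect_equal(m2$precision, 0.9)
  m3 <- compute_metrics(confusion_counts(tn = 4))
  expect_true(is.na(m3$sensitivity))
  expect_true(is.na(m3$precision))
  # agreement with an independent fraction computation
  set.seed(5)
  for (i in 1:50) {
    v <- sample(0:40, 4, replace = TRUE)
    mm <- compute_metrics(confusion_counts(v[1], v[2], v[3], v[4]))
    ref <- function(n, d) if (d == 0) NA_real_ else n / d
    expect_equal(mm$accuracy, ref(v[1] + v[3], sum(v)), tolerance = 1e-12)
    expect_equal(mm$sensitivity, ref(v[1], v[1] + v[4]), tolerance = 1e-12)
    expect_equal(mm$specificity, ref(v[3], v[3] + v[2]), tolerance = 1e-12)
    expect_equal(mm$precision, ref(v[1], v[1] + v[2]), tolerance = 1e-12)
  }
})

test_that("stream scoring matches detections to intervals by sample overlap", {
  iv <- data.frame(start_index = c(1, 101, 201), end_index = c(100, 150, 300),
                   label = c("walk", "fall", "walk"),
                   polarity = c("non-fall", "fall", "non-fall"))
  one <- data.frame(start_index = 120, end_index = 140)
  expect_equal(unclass(score_stream(iv, one)),
               list(tp = 1, fp = 0, tn = 2, fn = 0))
  two <- data.frame(start_index = c(110, 130), end_index = c(120, 145))
  expect_equal(unclass(score_stream(iv, two)),
               list(tp = 1, fp = 1, tn = 2, fn = 0))   # extra detection is FP
  stray <- data.frame(start_index = 10, end_index = 20)
  expect_equal(unclass(score_stream(iv, stray)),
               list(tp = 0, fp = 1, tn = 1, fn = 1))   # walking hit -> FP
  none <- data.frame(start_index = integer(), end_index = integer())
  expect_equal(unclass(score_stream(iv, none)),
               list(tp = 0, fp = 0, tn = 2, fn = 1))
})

test_that("near-fall polarity is a choice of the evaluator, not hard-coded", {
  iv <- data.frame(start_index = 1, end_index = 50, polarity = "near-fall")
  det <- data.frame(start_index = 10, end_index = 20)
  as_neg <- score_stream(iv, det)
  expect_equal(as_neg$fp, 1)
  as_pos <- score_stream(iv, det, positive_labels = c("fall", "near-fall"))
  expect_equal(as_pos$tp, 1)
})

test_that("TP + FN equals the number of fall trials on a synthetic suite", {
  trials <- synthetic_benchmark(n_fall = 8, n_adl = 8, seed = 6)
  total <- confusion_counts()
  for (tr in trials) {
    total <- total + score_trial(tr$label, nrow(find_falls(tr$series)$accepted))
  }
  expect_equal(total$tp + total$fn, 8)
  expect_lte(total$tn, 8)
})

test_that("threshold sweeps report one deterministic row per combination", {
  trials <- synthetic_benchmark(n_fall = 3, n_adl = 3, seed = 9)
  g1 <- data.frame(min_limit = 6.5)
  s1 <- sweep_thresholds(g1, trials)
  expect_equal(nrow(s1), 1)
  expect_equal(s1$fpr, 1 - s1$specificity)

  # unused thresholds cannot change metrics on a candidate-free trace
  rest <- list(fall_trial(series_from_magnitudes(rep(standard_gravity, 200)),
                          label = "non-fall"))
  g2 <- data.frame(dist_1 = c(50, 150))
  s2 <- sweep_thresholds(g2, rest)
  expect_equal(s2$tn, c(1, 1))
  expect_equal(s2$accuracy[1], s2$accuracy[2])
  expect_error(sweep_thresholds(data.frame(), trials), "non-empty")
  expect_error(sweep_thresholds(data.frame(bogus = 1), trials), "unknown threshold")
})

test_that("sub-class tallies expose the final checks' contribution", {
  # craft a confounder the final checks reject: a dip-spike pair followed by a
  # sustained larger oscillating disturbance (peak dominated, aftermath not at g)
  m <- rep(standard_gravity, 700)
  m[101:110] <- 3
  m[131] <- 35
  m[141:260] <- standard_gravity + rep(c(10, -2.5), length.out = 120)
  m[200] <- 45  # dominating neighbour within dist_2 of the spike
  confound <- fall_trial(series_from_magnitudes(m), label = "non-fall",
                         sub_class = "stumble-like")
  trials <- c(synthetic_benchmark(n_fall = 3, n_adl = 2, seed = 14),
              list(confound))
  tab <- tally_subclasses(trials)
  row <- tab[tab$sub_class == "stumble-like", ]
  expect_equal(row$false, 0)     # rejected by the final checks
  expect_gte(row$false_2, 1)     # but counted when they are disabled
  expect_equal(sum(tab$total), length(trials))
  fall_row <- tab[tab$sub_class == "fall", ]
  expect_equal(fall_row$true, 3)
})
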