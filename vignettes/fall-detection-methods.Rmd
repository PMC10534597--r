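---
title: "Threshold-based fall detection: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Threshold-based fall detection: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(accelfall)
```

## The signal model

A worn tri-axial accelerometer at rest reads standard gravity. Because the
device's orientation on the body is unknown, the detector never looks at the
individual axes: it works on the per-sample *sum vector magnitude*

$$m_n = \sqrt{x_n^2 + y_n^2 + z_n^2},$$

which is invariant under any rotation of the sensor. A fall has a
characteristic magnitude signature: a brief **dip** well below gravity while
the body is in free-fall-like motion, a sharp **spike** well above gravity at
impact a fraction of a second later, and then a quiet stretch **settling at
g** while the person lies still. Daily activities produce oscillations
(walking, jogging), isolated spikes without a preceding dip (a jump), or
shallow excursions (sitting down), none of which show the full
dip-then-spike-then-quiet pattern.

## Frequency-normalized time: entries

All temporal thresholds are expressed in *entry units* rather than seconds so
that one threshold set works at any sampling rate. Entries are a
pseudo-timestamp built recursively:

$$\mathrm{entry}_1 = 0,\qquad
  \mathrm{entry}_n = \frac{t_n - t_{n-1}}{10} + \mathrm{entry}_{n-1}
    + \frac{100}{f},$$

with $t_n$ in seconds and $f$ the nominal frequency in Hz. At ideal
timestamps the fixed term contributes 100 units per second at any frequency,
and the $\Delta t / 10$ term adds a small correction for timing jitter and
gaps, so entries advance at about 100.1 units per second; **100 entry units
correspond to roughly one second** (0.999 s at 100 Hz). The package feeds
*seconds* into the recursion: that is the only unit under which the
calibration just stated holds, and all entry-valued defaults below (50 ≈ 0.5
s, 100 ≈ 1 s) rely on it. For files that ship no timing information,
timestamps are synthesized as $(i-1)/f$.

The classification loop examines every sample, including the first; a fall
whose dip begins exactly at the first sample is therefore still eligible.

## Stage one: candidate detection

1. **Classification.** A magnitude is *low* when strictly below `min_limit`
   and *high* when strictly above `max_limit`; boundary values are neither.
2. **Clustering.** Consecutive lows (or highs) form a set as long as the
   entry gap between neighbours is at most `sub_1`; a strictly larger gap
   starts a new set. A set may hold a single sample. Each set is kept as its
   first and last member.
3. **Connection.** Every low set whose first entry precedes a high set's last
   entry by at most `fall_duration` produces a *candidate fall* spanning
   first-low to last-high. Only forward pairings (lows before highs) are
   formed, matching the dip-then-spike signature; a reversed pairing would be
   a pattern the model never exhibits. One set may take part in several
   candidates at this stage.

## Stage two: validation

1. **Shared extremes.** Candidates sharing a low or high set are resolved in
   favour of the shorter time range. Naive pairwise deletion ("whenever two
   candidates share a set, delete the longer") is order-dependent when
   sharing is chained (A shorter than B, B shorter than C, A and C disjoint),
   so the package determinizes it greedily: repeatedly keep the globally
   shortest remaining candidate — ties broken by earlier start, then by
   construction order — and discard everything sharing one of its sets. For
   the simple two-candidates-one-set case this reduces exactly to "the
   shorter fall is accepted".
2. **Long falls.** A candidate whose span exceeds `fall_limitation` is
   *long*. If some classified-low sample closer to the impact brings the span
   within the limit, the start point is shifted to the qualifying low with
   the largest entry (the one closest to the impact) and the peak is
   recomputed; otherwise the candidate is rejected — a real fall happens in a
   short period of time.
3. **Final checks.** A surviving candidate is accepted iff at least one
   assumption holds:
   * **Stability:** over the samples whose entries lie within
     `stability_window` after the fall's end, the mean magnitude is within
     `mean_tol` of g and the standard deviation is at most `std_tol` — the
     person is on the ground and still. An empty window (fall at the very end
     of the recording) is insufficient evidence and fails this check.
   * **Peak dominance:** the fall's peak strictly exceeds every magnitude
     above `max_limit_2` within `dist_1` before its start or `dist_2` after
     its end. An equally tall neighbour defeats the check; with no
     neighbouring high it holds vacuously. The comparison is against raw
     neighbouring samples, the stricter of the two possible readings.
4. **Overlap resolution.** The three checks alone do not guarantee that
   accepted falls are disjoint in time: survivors with disjoint set usage can
   still overlap when the bridging candidate that would have linked them was
   itself consumed by an even shorter rival. A final pass keeps the shorter
   of any two overlapping accepted falls (tie: earlier start). In practice
   this fires only in adversarial geometries; it exists so the report's
   non-overlap guarantee is unconditional.

Running validation on its own accepted output changes nothing (idempotence),
and validation never creates a fall that detection did not propose.

## The thresholds

| name | default | unit | meaning |
|---|---|---|---|
| `min_limit` | 6.5 | m/s² | upper bound for a *low* magnitude |
| `max_limit` | max(mean(m), 20) + 10 | m/s² | lower bound for a *high*, resolved once per series |
| `sub_1` | 50 | entries | gap that splits two sets (≈ 0.5 s) |
| `fall_duration` | 105 | entries | longest low-to-high span forming a candidate |
| `fall_limitation` | 85 | entries | span above which a fall is long |
| `dist_1`, `dist_2` | 100 | entries | neighbourhood searched for rival peaks |
| `max_limit_2` | = `max_limit` | m/s² | high threshold for neighbouring samples |

The adaptive `max_limit` rule is evaluated over *all* magnitudes of the input
series, once; there is no windowed variant. For a mostly-at-rest recording the
mean sits near g, the `max(·, 20)` guard binds, and the resolved limit is
30 m/s². Raising `max_limit_2` above `max_limit` only loosens the peak check;
values below `max_limit` would be meaningless for it, so the default keeps
equality.

The stability check's tolerances are qualitative in the method's description
("close to g", "low" deviation). The package fixes `mean_tol = 1.5` m/s²,
`std_tol = 2.0` m/s² and `stability_window = dist_2` (≈ 1 s) — the window
reuses an existing calibrated constant rather than introducing an unrelated
ninth threshold. These three are package defaults, clearly separated from the
tuned thresholds above, and are exposed in the YAML config like everything
else. Configs round-trip losslessly (numerics are written with 17 significant
digits).

## The synthetic generator

`generate_scenario()` scripts a magnitude profile — rest at g, plus events —
then adds i.i.d. Gaussian noise to the magnitude and distributes each
magnitude over x/y/z along a random unit vector, so the scripted magnitude is
preserved exactly while the per-axis signals are uninformative, mimicking an
arbitrarily-oriented sensor. Defaults, fixed once:

* sampling 100 Hz; magnitude noise `noise_sd = 0.2` m/s² (typical rest jitter
  of a worn MEMS accelerometer), capped at 0.3 m/s² during the 1.5 s
  post-impact settling window;
* a fall is a dip uniform in [1, 5.5] m/s² lasting 0.1–0.3 s, a spike in
  [35, 60] m/s² of 1–3 samples starting 0.15–0.6 s after the dip (the
  near-g baseline resolves `max_limit` to 30, so spikes clear it by ≥ 5),
  then ≥ 1.5 s of rest;
* walking/jogging are sinusoids (1.8 / 2.8 Hz) whose amplitudes keep the
  magnitude strictly inside (`min_limit`, `max_limit`); a jump is a spike
  with a smaller earlier peak and *no* qualifying dip; sitting is a shallow
  dip above `min_limit` plus a mild bump.

Each scenario is fully determined by its seed, and generation leaves the
caller's RNG state untouched. What the generator does **not** emulate:
biomechanically realistic falls, orientation drift during body rotation,
sensor saturation, or the near-fall/stumble morphologies that are the
method's documented weak spot on real data. Tests passing on this generator
therefore demonstrate that the implementation realizes the intended pattern
logic, not that the headline field performance transfers to any particular
real dataset.

## Evaluation semantics

Per-trial scoring uses the multiple-detection rule: on a fall trial the first
detection is the TP and each surplus detection an FP; on a non-fall trial
every detection is an FP. Consequently TP + FN equals the number of fall
trials while FP is unbounded by the trial count. For continuous labeled
streams, a detection claims the first unmatched overlapping fall interval
(overlap = at least one shared sample, the simplest rule consistent with
per-interval counting); everything else it touches makes it an FP, unmatched
fall intervals are FNs, and untouched non-fall intervals are TNs. Whether a
"near fall" class counts as positive is an evaluator option, not a constant.
Metrics with empty denominators are reported as not-available, never as 0.
`tally_subclasses()` additionally reports each class's error count with the
final checks disabled, quantifying how much the last validation stage
contributes.

## Numerical and scale choices

All magnitude/entry arithmetic is double precision with no intermediate
rounding. Degenerate inputs fail fast with informative errors (empty series,
non-increasing timestamps, non-positive frequency). Test and acceptance
problem sizes — random series up to 400 samples for the 1000-case oracle
equivalence sweep, 100-scenario stochastic batches, a 120-trial benchmark —
were chosen as the smallest sizes at which every code path (sharing chains,
shrinking, both final checks, overlap pruning) is exercised; the full suite
runs in well under a minute.

## Known limitations

* Whole-series processing only: the adaptive `max_limit` needs the complete
  recording, so there is no bounded-memory streaming mode.
* Activities whose magnitude pattern genuinely matches dip-then-spike
  (stumbles, collapsing into a chair, near-falls) are accepted by design;
  jogging-style continuous lows can conversely mask a real fall's dip. These
  are properties of the method, reproduced faithfully.
* The exact CSV headers of the public datasets are not standardized; the
  shipped dialect defaults should be checked against each dataset's own
  documentation before a real-data run.
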