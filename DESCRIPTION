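Package: accelfall
Title: Threshold-Based Human Fall Detection from Tri-Axial Accelerometer Streams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects human falls in three-axis accelerometer time series with a
    two-stage threshold method. Stage one classifies sum-vector-magnitude extremes
    as low or high, clusters them into sets over a frequency-normalized pseudo-time
    ("entries"), and connects low sets to high sets into candidate falls; stage two
    resolves candidates that share extremes, shrinks or rejects over-long falls, and
    accepts a candidate when the post-impact signal settles near gravity or its peak
    dominates neighbouring peaks. Includes readers for common public fall-detection
    dataset layouts, a seeded synthetic trace generator with ground truth, and a
    confusion-matrix evaluation harness with threshold sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
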