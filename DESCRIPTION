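Package: thalaxon
Title: Analysis of Thalamocortical Axon Calcium Signals in a Two-Whisker Discrimination Task
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trial-based analysis of two-photon GCaMP6s calcium signals from
    thalamocortical axons imaged during a go/no-go two-whisker discrimination
    task, together with a seeded synthetic-session generator for validation.
    Covers correlation-based merging of axonal ROI segments with pixel-weighted
    neuropil subtraction, piecewise-mode baseline estimation with polynomial
    smoothing, noise estimation from negative fluctuations, trial-aligned
    z-scoring, per-bin one-sided z-tests with consecutive-bin significance and
    latency calls, whisker selectivity indices, 90% confidence-ellipse overlap
    of tuned pixel populations, and single-trial response-latency correlation
    with lick reaction times.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pracma,
    mclust,
    jsonlite,
    optparse
Config/testthat/edition: 3
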