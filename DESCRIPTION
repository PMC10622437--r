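Package: wmtrace
Title: Trial-Aligned Calcium Trace Analysis for Working-Memory Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Event-anchored analysis of fiber-photometry and miniscope
    calcium recordings from trial-structured working-memory behavior.
    Provides segment-wise temporal resampling of traces onto a common
    task-phase timebase, per-unit task-phase preference statistics with
    rank-sum tests and co-activity matrices, time-resolved ROC decoding
    of trial types against trial-shuffle nulls with Benjamini-Yekutieli
    correction, train/test validation of delay-period neuronal sequences,
    the Binary Directed Orderability (BDO/ABDO) statistic with its
    per-trial label-shuffle permutation test, and L2-norm transient
    population decoding.  A seeded synthetic-session generator emulates
    the trial grammar, phase-tuned subpopulations and delay sequences
    these analyses assume, so the whole pipeline is testable without
    recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
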