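Package: fatiguekit
Title: Handgrip Fatigue Quantification and Bilateral Movement-Quality Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for quantifying muscle fatigue from cued handgrip force and
    surface EMG recordings, and for assessing bilateral movement quality from a
    virtual object-hit task. Implements FWHM-median quantification of maximum
    voluntary contractions, per-contraction area-under-the-curve fatigue slopes,
    Butterworth filtering and envelope extraction for EMG, kinematic outcome
    measures (hits, speed, absolute acceleration, space covered), within-subject
    ANOVA with effect sizes, and a cluster-based permutation test for
    two-dimensional spatial maps. A seeded synthetic-data generator emulates the
    fatiguing-task and object-hit protocols so the full pipeline can be
    exercised and validated without access to participant recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
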