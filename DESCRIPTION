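Package: loglogstep
Title: Step Analysis of Log-Log Correlation Integrals for Pattern
    Detection in Event-Interval Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects short repeating patterns in noise- and
    jitter-contaminated event-interval (interspike-interval) series via
    staircase structure in the log-log plot of the correlation integral.
    Provides delay-coordinate embedding and a fast maximum-norm
    correlation integral over a logarithmic radius grid, derivative-based
    step and plateau detection with three weighted quality criteria
    (single-step visibility with surrogate comparison, exact peak-count
    visibility, and plateau-flatness difference between consecutive
    embedding dimensions), analytical lower and upper bounds on the
    number of observable steps in the noiseless case together with a
    brute-force oracle, a configurable simulator for patterned interval
    series under jitter and two noise-insertion paradigms, permutation
    surrogates, and jitter-by-noise phase-diagram sweeps with region
    classification.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
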