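Package: rpmeta
Title: Rank-Product Meta-Analysis of Multi-Study Expression Data
Version: 0.1.0
Authors@R:
    person("rpmeta", "maintainers", email = "rpmeta@example.org", role = c("aut", "cre"))
Description: Cross-study rank-product meta-analysis for log-scale expression
    matrices: the geometric-mean-rank statistic over all cross-group sample
    pairs, permutation-based empirical p-values, pairwise group tests between
    normal, low-grade and high-grade tumor samples, and classification of
    probes into twelve cross-test expression-ordering patterns. Also provides
    in-cohort biopsy statistics (Welch and pooled t-tests, one-way ANOVA,
    Tukey-Kramer post hoc comparisons, Benjamini-Hochberg FDR), xenograft
    growth kinetics (ellipsoid tumor volume and log-linear doubling time), and
    a synthetic-data generator that plants differential-expression patterns in
    multi-study collections for power and calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
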