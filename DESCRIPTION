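Package: ofadif
Title: Score-Based Parameter Instability Tests for Ordinal Factor Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ordinal (confirmatory) factor analysis for graded response
    models estimated by the limited-information route: univariate probit
    thresholds, Olsson two-step polychoric correlations and weighted least
    squares (WLS) minimization of the moment discrepancy. Provides an
    approximated per-person score function for such fits, the decorrelated
    cumulative score process, and the family of score-based parameter
    instability tests (DM, CvM, maxLM, LMuo, WDMo, maxLMo) for detecting
    differential item functioning against metric, ordinal and categorical
    person covariates. Includes a graded-response-model simulator with
    focal/reference DIF scenarios, NCDIF effect sizes, and a replication
    harness for Type I error and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    mvtnorm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    numDeriv,
    optparse
Config/testthat/edition: 3
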