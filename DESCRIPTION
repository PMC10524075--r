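Package: fitriage
Title: Diagnostic Accuracy of Triage Screening Tests with Bivariate
    Meta-Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating two-stage (triage) cancer-screening
    programmes that combine a questionnaire-based risk assessment with a
    fecal immunochemical test. Encodes the high-risk decision rule, the
    parallel and serial test-combination strategies, and the
    screen-detected / missed / interval outcome classification that turn a
    screening cohort into 2x2 confusion tables; computes sensitivity,
    specificity, predictive values, likelihood ratios and detection rates
    with confidence intervals; and implements the diagnostic-test-accuracy
    meta-analysis stack from first principles: bivariate random-effects
    pooling of logit sensitivity and specificity (REML and exact-binomial
    maximum likelihood), pooled likelihood ratios, summary ROC curves with
    AUC, random-effects proportion pooling, Cochran Q and I-squared,
    bivariate meta-regression, Deeks' funnel-plot asymmetry test, and
    Fagan pre/post-test probability arithmetic. Includes seedable
    generators for synthetic screening cohorts and study collections so
    the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    metafor,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
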