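Package: muacprobit
Title: PROBIT Estimation of Acute-Malnutrition Prevalence from MUAC
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating the prevalence of acute malnutrition in
    children under five from mid-upper arm circumference (MUAC) measurements.
    Implements the classic design-based proportion estimator with
    cluster-adjusted standard errors and two PROBIT estimators that convert
    the sample mean (and either an external or the sample standard deviation)
    of MUAC into the normal cumulative probability below a case-defining
    cutoff, with cluster-bootstrap confidence intervals. Includes a synthetic
    two-stage cluster survey generator, a small-sample survey simulator, and
    Monte-Carlo evaluation of bias, precision, coverage and threshold
    classification, so the estimators can be compared under controlled
    conditions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    broom,
    optparse,
    testthat (>= 3.0.0),
    tidyr
Config/testthat/edition: 3
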