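Package: wcescreen
Title: Weighted Cumulative Exposure Screening for Drug Safety Signals in Claims Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A data-driven pharmacovigilance pipeline that screens every health
    event (drug initiation, procedure, diagnosis) occurring after first exposure
    to a drug of interest for association with weighted cumulative exposure
    (WCE) to that drug. The hazard of each candidate event is modelled with a
    time-dependent Cox model in which the log-hazard contribution of a dose
    taken v months ago is a cubic regression spline in v; association is tested
    with a nonparametric patient-level bootstrap using percentile confidence
    intervals. A case-crossover comparator (one risk period, three control
    periods, one-month washouts, conditional logistic estimation) and a seeded
    synthetic claims generator with known ground truth are included, so the
    whole pipeline can be exercised and calibrated without access to real
    claims data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    splines,
    stats,
    utils,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    survival,
    optparse,
    jsonlite
Config/testthat/edition: 3
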