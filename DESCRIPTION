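Package: catchuptime
Title: Natural-History Models for Cancer-Screening Sojourn and Lead Time
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two competing natural-history models of cancer screening and the
    estimators built on them. The catch-up time model assumes the time of
    clinical diagnosis is independent of the sojourn time in the preclinical
    detectable phase; the classic Markov model assumes independence between
    preclinical onset and sojourn time. The package provides closed-form and
    root-finding estimators of mean sojourn time from first-screen detection
    rates and background incidence (catch-up time, moment, and
    prevalence/incidence methods) with Poisson confidence intervals, joint
    Poisson maximum-likelihood estimation of mean sojourn time and test
    sensitivity from screening-trial count tables, interval-cancer incidence
    prediction under both models, length-biased lead-time computation, a
    Volterra deconvolution of preclinical onset incidence, and an
    individual-level trial simulator used as the validation oracle. Worked
    prostate (ERSPC-Rotterdam) and breast (HIP) screening examples ship as
    plain-text fixtures.
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
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
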