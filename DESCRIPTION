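Package: synthprev
Title: Model-Based Synthetic Estimation of Small-Area Prevalence from Survey Microdata
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for forecasting area-level prevalence of binary health
    outcomes (such as perceived and unmet mental health needs) from survey
    microdata by regression synthetic estimation. Individual-level
    random-intercept logistic models are fitted on respondent records nested
    in health regions, reduced by backward selection on information criteria,
    assessed for discrimination (weighted C statistic) and calibration
    (calibration slope, decile calibration tables), and converted into
    area-level synthetic estimates by applying the fitted coefficients to
    area-level predictor proportions. Includes a survey microdata simulator
    with design weights and Rao-Wu-Yue rescaled bootstrap replicate weights,
    survey-weighted descriptive estimators with replicate-weight variance,
    observed-versus-predicted validation, and an end-to-end pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    yaml,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
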