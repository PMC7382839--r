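Package: pafburden
Title: Population Attributable Fractions for Cancer Burden from Lifestyle Risk Factors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative risk assessment toolkit for attributing cancer cases
    and deaths to modifiable lifestyle risk factors (alcohol consumption, high
    body mass index, low fruit and vegetable consumption, lack of physical
    activity, tobacco smoking and passive smoking). Derives categorized
    exposure prevalence from survey-style records, computes population
    attributable fractions (PAFs) for categorical exposures and for continuous
    BMI by numerical integration of a dose-response relative-risk curve against
    a theoretical-minimum-risk counterfactual, combines fractions across
    independent risk factors, and aggregates attributable counts across sexes
    and cancer sites. Ships the published Chilean 2018 prevalence, PAF and
    occurrence tables as plain-text fixtures, plus a synthetic survey-data
    generator with analytically known ground-truth PAFs for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    readr,
    jsonlite,
    pracma,
    stats,
    utils,
    rlang
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
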