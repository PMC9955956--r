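Package: rxvar
Title: Practice Variation Analysis of Chronic Opioid Prescribing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for quantifying between-practice variation in chronic
    and chronic high-dose opioid prescribing from primary-care dispensing
    records. Builds per-patient opioid exposure episodes from ATC-coded
    prescriptions, converts doses to oral morphine equivalents (OME),
    classifies patient-years as chronic (>=90 consecutive covered days) or
    chronic high-dose (>=90 mg OME/day on such an episode), computes
    indirectly case-mix-standardized practice proportions via logistic
    regression observed/expected ratios, summarises variation with
    percentile and top-10/bottom-10 ratios, draws funnel plots with
    winsorized overdispersion-adjusted control limits, and profiles outlying
    practices against size, socioeconomic status and urbanicity. Includes a
    synthetic cohort generator with ground-truth labels for validating every
    stage end-to-end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    stringr,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown,
    jsonlite
Config/testthat/edition: 3
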