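Package: icptrend
Title: Postoperative Intracranial Pressure Trend Analysis for ETV Outcome
    Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analyzing early postoperative intracranial pressure
    (ICP) monitoring after endoscopic third ventriculostomy (ETV) in infantile
    hydrocephalus. Hourly ICP recordings are summarized into daily average
    values (DAV) over the first three postoperative days, each patient's
    trajectory is classified as stable or progressively increasing at a swept
    set of margins, and the resulting trend is evaluated as a diagnostic test
    for six-month ETV outcome (sensitivity, specificity, predictive values
    with exact Clopper-Pearson confidence intervals, and Pearson chi-square
    on the trend-by-outcome table). A seedable synthetic-cohort generator
    reproduces the statistical structure of such studies so the full pipeline
    is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
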