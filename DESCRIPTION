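Package: excesscost
Title: Excess Length-of-Stay Costing for Hospital Episode Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Attributes the cost of above-average hospital length of stay to
    patient complexity. Codes administrative discharge episodes for dementia
    (person-linked lookback), a modified Charlson comorbidity index, and four
    nurse-sensitive hospital-acquired complications with aetiology exclusions;
    decomposes Diagnosis Related Group (DRG) costs into per-day variable and
    one-off fixed components to price each episode's extra days; and fits a
    two-step hierarchical linear model on log excess cost, reporting
    standardised betas, back-transformed dollar effects and
    percentage-of-mean-cost summaries. A synthetic episode generator with
    known log-linear effects supports end-to-end parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
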