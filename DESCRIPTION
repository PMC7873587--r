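Package: cltsce
Title: Societal Cost-Effectiveness Analysis of Community-Led Total
    Sanitation Interventions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for retrospective societal cost-effectiveness analysis of
    community-led total sanitation (CLTS) programs. Implements bottom-up
    activity-based costing with value-of-time monetization, observation-
    validated classification of household sanitation outcomes (open
    defecation and usable-latrine ownership), cost-effectiveness and
    incremental cost-effectiveness ratios with explicit handling of
    worsened outcomes, and Monte Carlo probabilistic sensitivity analysis
    with percentile confidence intervals. Includes a calibrated synthetic
    household-survey and cost-ledger generator so the full pipeline can be
    exercised without access to primary survey data, plus a bundled fixture
    encoding the published cost-category amounts and outcome counts of a
    four-intervention CLTS evaluation in Ethiopia and Ghana.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
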