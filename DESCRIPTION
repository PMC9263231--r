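Package: sradispro
Title: Disproportionality Analysis of Spontaneous Adverse-Event Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for pharmacovigilance signal detection from individual case
    safety reports: a tidy line-listing data model with readers, writers and
    de-duplication; 2x2 contingency construction for drug-event and drug
    class-event pairs with ATC-style class pooling; reporting odds ratios with
    Woolf confidence intervals and Haldane-Anscombe correction; the shrinkage
    observed-to-expected information component with its gamma lower
    credibility bound (IC025) and the classical IC025 > 0, n >= 30 signal
    criteria; case-cohort descriptive summaries (demographics, seriousness,
    outcomes, time to onset, co-reported terms); and a seeded generator of
    synthetic spontaneous-reporting databases with known injected drug-event
    associations for calibration and parameter-recovery studies.
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
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
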