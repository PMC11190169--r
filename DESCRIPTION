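Package: faersignal
Title: Disproportionality Signal Detection for FAERS Spontaneous Adverse Event Reports
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for pharmacovigilance signal detection in FDA Adverse
    Event Reporting System (FAERS) style spontaneous-report data. Parses
    dollar-delimited quarterly report tables, deduplicates case versions,
    maps reaction preferred terms to system organ classes, builds drug-event
    2x2 contingency tables, and computes four disproportionality statistics
    (reporting odds ratio, proportional reporting ratio with Pearson
    chi-square, BCPNN information component, and the empirical Bayes
    geometric mean) with confidence bounds and the standard positive-signal
    criteria. Includes clinical-characteristics profiling of a drug's
    report set and a
    synthetic report generator with planted drug-event associations so the
    whole pipeline is testable without any database download.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
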