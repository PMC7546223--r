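Package: panelval
Title: Quality Gates, Dual-Pool Variant Filtering and Concordance Analysis
    for a Targeted Tumor Amplicon Panel
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reusable workflow for the clinical validation of a 26-gene
    dual-pool amplicon sequencing panel on FFPE tumor specimens.  Implements
    the pre-sequencing quality gates (tumor-cell content, delta-Cq DNA
    amplifiability, library fragment size), merging and PASS/REVIEW/EXCLUDED
    filtering of paired pool-A/pool-B variant calls, per-amplicon and
    per-exon coverage assessment with cross-pool compensation,
    diagnostic-accuracy concordance against an orthogonal reference standard
    with exact Clopper-Pearson confidence intervals, and a seeded synthetic
    FFPE-cohort generator so that every stage is testable without patient
    data.  All user-facing functions take data frames and return tibbles.
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
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
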