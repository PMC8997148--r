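Package: varmedal
Title: Medal-Based Germline Variant Prioritization for Cancer Gene Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Prioritizes germline variants from exome cohorts of cancer
    patients using a four-tier "medal" classification (Gold, Silver, Bronze,
    Unknown) over a configurable cancer predisposition gene panel. Implements
    caller-level quality filters (depth, allele balance, population
    frequency), evidence-based medal assignment from pathogenicity
    assertions, somatic-catalogue refinement of Silver calls, cohort-level
    curation of mapping artifacts and cohort-common variants, loss-of-function
    intolerance (pLI) and C-terminal truncation triage, per-patient carrier
    summaries, and carrier association and survival statistics. Ships a
    curated 50-row Gold-variant table and a seeded synthetic-cohort generator
    (per-patient VCFs, evidence tables, covariates, survival times, truth
    labels) for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    stats,
    survival,
    tibble,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
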