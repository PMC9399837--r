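Package: fusetriage
Title: Triage of Gene-Fusion Calls from Targeted RNA Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-sequencing prioritization of gene-fusion calls from
    targeted RNA panels. Annotates fusion breakpoints against a transcript
    model, determines the reading frame of the chimeric coding sequence and
    the retention of functional protein domains (kinase, transactivation,
    DNA-binding), deduplicates supporting reads by molecular barcode, and
    applies an artifact/passenger/known-fusion filter cascade to classify
    every call as artifact, passenger, known oncogenic, or novel candidate.
    Includes cohort-level reporting (per-group detection frequency,
    recurrence, novel-fusion inventory) and a synthetic-cohort generator
    with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    tibble,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
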