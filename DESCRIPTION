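Package: dcctools
Title: Pathway Activity, Differential Expression and Copy-Number
    Frequency Profiles for Rare Disseminated Cancer Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical pipeline for transcriptome and copy-number profiles
    of rare bone-marrow disseminated cancer cells (DCCs) and related mammary
    cell populations.  Implements per-cell pathway membership enrichment by
    one-tailed Fisher exact tests on expressed-gene contingency tables,
    empirical-Bayes moderated-t differential expression with exact
    FDR/fold-change calling rules, non-centered fold-change concordance
    between contrast signatures, core-gene partitioning of enriched pathways,
    and stratified cumulative gain/loss frequency profiles from per-cell
    copy-number aberration calls.  Ships seeded synthetic-data generators
    that emulate the structure of single-cell and small-replicate microarray
    cohorts so every stage is testable without controlled-access data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    fgsea,
    generics,
    ggplot2,
    IRanges,
    jsonlite,
    limma,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
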