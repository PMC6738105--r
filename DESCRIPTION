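Package: cotarget
Title: Driver-Gene Co-Expression Screening, Pre-Ranked Enrichment and
    Prognostic Metagene Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A multi-cohort discovery pipeline for nominating transcriptional
    targets of a driver gene from bulk expression data. Screens every gene for
    Pearson correlation with the driver in each cohort with Benjamini-Hochberg
    false discovery control, intersects cohorts with a sign-consistency rule and
    tests the activator-versus-repressor imbalance by Fisher's exact test; runs
    pre-ranked gene-set enrichment (weighted Kolmogorov-Smirnov running sum,
    gene-label permutation, normalised enrichment scores and permutation-based
    FDR) and intersects leading edges into a core target list; scores a
    prognostic metagene and evaluates it by Kaplan-Meier, log-rank and Cox
    proportional-hazards models; intersects human candidates with a knockout
    differential-expression table across species; and annotates ChIP-seq peaks
    to gene windows. A synthetic-data module generates every input with known
    ground truth so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    stringr,
    survival,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    fgsea,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
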