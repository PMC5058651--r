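Package: cdclossmap
Title: Somatic Alteration Calling and Multi-Assay Integration for
    Collecting Duct Carcinoma Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tumor/normal somatic variant filtering (normal-absence,
    one-sided Fisher enrichment, strand-orientation, homopolymer-context
    and indel-realignment filters), gene-level copy-number loss calling
    from logR segments, FISH probe-ratio classification of CDKN2A status,
    integration of array, sequencing and FISH evidence into per-sample
    gene status with cohort frequencies, and solute-carrier (SLC) family
    expression profiling.  Ships a seeded synthetic tumor/normal cohort
    generator with ground-truth labels so the whole pipeline is testable
    end to end, plus a command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
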