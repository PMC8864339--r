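Package: lowdetect
Title: Detecting Mosaic Loss of the W Chromosome from Targeted Amplicon
    Sequencing Coverage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A desk-scale pipeline for detecting age-related mosaic loss of
    the avian W chromosome (LOW) from targeted PCR and sequencing coverage.
    Covers W-linked sequence discovery by male/female k-mer read subtraction
    with a minimal unitig builder, gametologue-aware primer screening,
    per-locus unique-read counting from SAM alignments or by alignment-free
    k-mer assignment, autosomal-normalized copy-number estimation calibrated
    on a nestling group, pairwise Mann-Whitney tests with Benjamini-Hochberg
    correction plus an age-trend linear model, a seeded synthetic-cohort and
    read simulator emulating the assay, and Monte-Carlo power analysis of the
    smallest detectable mosaic-loss fraction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rsamtools,
    S4Vectors,
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
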