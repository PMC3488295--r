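Package: xenqc
Title: Quality Control and Accounting for Xenopus Expressed-Sequence Resources
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for auditing the expressed-sequence resources of a model
    organism: longest-ORF detection and transcript completeness classification
    for gene-model transcripts, repeat-coverage filtering, full-insert cDNA
    clone quality control against reference EST contigs (frameshift, chimera,
    truncation and retained-intron calling), genome-assembly gap statistics,
    clone-set to gene coverage accounting, and submission-metadata mining from
    GenBank flatfiles. Includes a deterministic synthetic-data generator with
    known ground truth for every classifier, and report renderers for the
    standard tally layouts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    dplyr,
    jsonlite,
    readr,
    tibble,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
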