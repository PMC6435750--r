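Package: picoclade
Title: Clade Delineation for Picophytoplankton V4 Metabarcoding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for delineating clades of marine
    picophytoplankton (Mamiellophyceae and similar groups) from 18S rRNA V4
    amplicon data: exact-sequence dereplication into amplicon single
    variants (ASVs), abundance-based selection of major ASVs and their
    cross-dataset confirmation by strict sequence identity, discovery of
    diagnostic alignment signatures and signature-based clade assignment,
    pairwise-identity summaries with OTU identity-threshold lumping
    analysis, dual-tree clade criteria (monophyly under two construction
    methods plus bootstrap support), relative-abundance biogeography with
    presence thresholds and latitudinal habitat summaries, in-silico qPCR
    primer and probe mismatch screening with degenerate-base support, and a
    synthetic-data generator that emulates the statistical structure of
    paired coastal metabarcoding datasets for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr,
    jsonlite
Config/testthat/edition: 3
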