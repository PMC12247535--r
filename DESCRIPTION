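Package: cogcn
Title: Concentration-Ordered Gene Co-Expression Network Analysis for
    Plant Transcription-Factor Families
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An analysis pipeline for genome-wide characterization of a
    plant transcription-factor gene family along an ordered stress
    gradient (e.g. NaCl concentration). Identifies family candidates by
    intersecting HMM-profile hits with identity-filtered BLAST hits and
    renames them by chromosomal position; computes protein
    physicochemical properties (molecular weight, isoelectric point,
    instability index, aliphatic index, GRAVY); extracts strand-aware
    upstream promoter regions and scans them for IUPAC-encoded
    cis-regulatory elements in three functional categories; filters and
    classifies TPM expression profiles across the gradient into four
    response patterns; builds a concentration-ordered co-expression
    network from Pearson correlations with bait-gene seeding and
    breadth-first-search level assignment; and tests gene sets for
    functional enrichment with the hypergeometric distribution and
    Benjamini-Hochberg correction. A deterministic synthetic-data module
    generates every input with planted ground truth so the whole
    pipeline can be exercised and verified offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    igraph,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
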