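Package: sexmark
Title: Sex-Linked Marker Discovery from Pooled Whole-Genome Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discovers male-specific sequences in dioecious (XX/XY) plant
    genomes from pooled male and female whole-genome resequencing reads.
    Implements AG-prefixed 35-mer counting per pool, count-threshold
    filtering, pure male-specific k-mer (MSK) selection, extraction of
    candidate read pairs, a minimal de Bruijn unitig assembler,
    zero-mismatch read map-back with depth-based scaffold classification
    (female-zero and 2x male-coverage rescue rules), in-silico PCR
    amplicon prediction for dominant sex markers, and contingency-table
    accuracy scoring of validation panels. Ships a seeded simulator for
    dioecious genomes, pooled paired-end reads, and marker-validation
    panels so the whole pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    data.table,
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
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
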