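Package: mitorder
Title: Mitochondrial Gene Order, Composition and Rearrangement Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Comparative analysis of animal mitochondrial genomes built around
    signed circular gene orders. Reads and writes annotated mitogenomes
    (GenBank flat files, FASTA, a plain-text gene-order format), computes
    per-genome composition statistics (A+T content by partition, gene
    overlaps, noncoding-region inventories with control-region detection),
    compares gene orders against the pancrustacean ground pattern
    (displaced-gene sets, breakpoint distances), infers stepwise
    rearrangement scenarios under an explicit event algebra (transposition,
    inversion, reverse transposition, tandem duplication/random loss, tRNA
    paralog remolding), quantifies tRNA paralog similarity by global
    alignment, assembles concatenated protein-coding supermatrices for
    external phylogenetic tools, and simulates fully specified synthetic
    mitogenomes and rearrangement histories for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
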