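Package: memalign
Title: MEM-Seeded Long Read Alignment with a Reduced FM-Index
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Seed-and-extend alignment of long sequencing reads to a
    reference genome. Maximal exact match (MEM) seeds of an automatically
    estimated minimal length are generated from a memory-reduced FM-index
    with a sampled suffix array; candidate mapping regions are scored by
    affine-gap Smith-Waterman, ranked, filtered by identity and read
    coverage, and reported in SAM with heuristic mapping qualities derived
    from the best and second-best region scores. Paired-end mapping adds
    seed pairing under strand and insert-size constraints and mate rescue.
    Includes a wgsim-style paired-read simulator with known truth and a
    recall/precision evaluator for verification on synthetic genomes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    parallel,
    Rcpp,
    Biostrings,
    IRanges,
    S4Vectors,
    BiocGenerics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Rsamtools,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
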