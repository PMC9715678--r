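Package: strandmod
Title: Strand-Aware Differential DNA Modification Analysis
Version: 0.1.0
Authors@R:
    person("strandmod", "maintainers", email = "strandmod@example.org",
           role = c("aut", "cre"))
Description: Window-level differential analysis of strand-specific
    MeDIP/hMeDIP-style sequencing data comparing two cell populations,
    with clustering of differentially modified 1-kb windows into regions
    by a gap/density rule, DNA-strand asymmetry statistics (asymmetry
    coefficient, multi-scale concordance curves, gene template-strand
    ratios, repeat-family asymmetry, CH sequence-content asymmetry),
    permutation (interval-shuffling) enrichment of transcription factor
    binding sites in significant windows, expression-stratified metagene
    profiles, and a planted-truth synthetic data generator used to
    validate every stage end-to-end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    data.table,
    jsonlite,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
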