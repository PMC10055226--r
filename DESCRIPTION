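Package: sirtascan
Title: Mapping Hotspots of De Novo Telomere Addition in Yeast Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies chromosomal sequences with a propensity to act as
    hotspots of de novo telomere addition (Sites of Repair-associated
    Telomere Addition, SiRTAs) by scoring telomere-like G/T tracts in
    sliding windows, merging above-threshold windows into scored regions,
    and annotating them with chromosome-arm orientation and genic context.
    Provides composition-preserving genome shuffling and Monte-Carlo null
    models for hotspot abundance and strand distribution, a permutation
    test for overlap enrichment between hotspot regions and genomic
    annotation sets, and a quantifier for pooled telomere-addition
    sequencing (PT-seq) reads that maps telomere-addition junctions at
    nucleotide resolution and calibrates read counts to per-clone
    efficiency. Includes synthetic genome and read simulators with
    machine-readable truth for validation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    Rsamtools,
    GenomicAlignments
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
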