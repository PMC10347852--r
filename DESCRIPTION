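Package: linklocal
Title: Barcode-Guided Local Assembly of Target Loci from Linked Reads
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reference-free local assembly of target loci from linked-read
    sequencing data (10x Chromium, stLFR, TELL-Seq, Haplotagging). Reads
    whose barcode is observed in the regions flanking a target are
    recruited genome-wide, assembled between anchor k-mers by a bounded
    breadth-first traversal of a de Bruijn graph, and vetted by aligning
    flank extensions of the assembled sequence back to the reference with
    a 90/90 identity/coverage gate, iterating over decreasing k-mer size
    and solidity threshold until a confident sequence is found. Includes a
    linked-read simulator (long molecules, barcodes, paired reads, truth
    tables and truth-placement BAMs) used throughout the test suite.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    parallel,
    Rcpp,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    Rsamtools,
    vcfR
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), jsonlite
biocViews: Sequencing, Assembly, StructuralVariation
Config/testthat/edition: 3
RoxygenNote: 7.3.3
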