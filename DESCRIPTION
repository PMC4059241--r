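Package: gdenoise
Title: Virtual HTS Genome Profiling and Repeat-Aware Variant Calling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Annotates a reference genome into unique (U) and multialigned
    (M) regions by generating an error-free virtual short read at every
    genomic position and exhaustively back-aligning the reads (all ungapped
    hits on both strands, up to a mismatch budget, in base space or SOLiD
    dinucleotide color space). Mismatched multialignments of the error-free
    reads expose the intragenomic single-nucleotide variants that
    distinguish near-identical repeat copies; the g-deNoise filter discards
    alignments carrying these annotated variants, converting cross-copy
    multialignments into unique placements and splitting M regions into
    deconvolutable (M_U) and locally identical (M_M) subregions. Strand- and
    start-point-aware SNP calling rules then recover acquired mutations in
    both unique and repeated regions of experimentally sequenced samples.
    Includes a seeded synthetic-fixture generator (planted repeat families,
    divergent sites, simulated error-bearing reads) so the whole pipeline is
    testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    data.table,
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    S4Vectors,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
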