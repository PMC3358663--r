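Package: spliceAgree
Title: Consensus Gene Structure Prediction from Transcript Clusters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts the exon-intron structure of a gene locus from a genomic
    sequence and a cluster of transcript (EST and mRNA) sequences. All spliced
    alignments of each transcript are represented implicitly through maximal
    pairings (maximal common-substring occurrences) and an embedding graph; a
    tailored graph visit enumerates biologically meaningful spliced
    compositions, a Minimum Factorization Agreement solver selects the minimum
    exon set explaining one composition per transcript, and a final step
    classifies introns by splice-site pattern (GT-AG, GC-AG, AT-AC) and
    spliceosome type (U2/U12) and reduces probable false-positive junctions
    onto supported ones. Includes a simulator of gene loci, isoforms and
    error-perturbed EST clusters, exporters to GTF/BED12/GFF3/JSON, and a
    command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    BiocGenerics
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
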