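Package: ampliclone
Title: Genotyping of CRISPR-Cas9 Edited Clones from Pooled Barcoded Amplicon Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A screening toolkit for clonal CRISPR-Cas9 editing experiments
    that pool up to 96 cell clones on one amplicon sequencing run using
    combinatorial row/column in-line barcodes. Provides plate-layout
    validation and well enumeration, dual-barcode demultiplexing of
    single-end reads in either orientation, an affine-gap glocal aligner
    tuned to preserve long cut-site deletions, indel/substitution allele
    calling with left-aligned canonical signatures, automated discrimination
    of sequencing artifacts from true alleles by strand bias and cross-well
    recurrence, clonal zygosity classification including mixed-clone
    detection, coverage-uniformity QC, and a read simulator with full ground
    truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    Rcpp,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Rsamtools,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
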