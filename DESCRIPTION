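Package: graftmobile
Title: Identification of Graft-Mobile mRNAs from Heterograft RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to identify mRNAs that move between the two genotypes of a
    heterografted plant from bulk RNA-seq. Implements genome-of-origin read
    classification with bounded-edit-distance semi-global alignment (two-edit
    first pass, one-edit second pass), a local-alignment cross-check that
    removes cross-mapping false positives, source-expression filtering and
    replicate-consensus calling of upwardly and downwardly mobile transcripts,
    transport-pattern classification across the one-grafted-plant/three-samples
    design, TPM quantification, and abundance-vs-mobility permutation tests.
    Ships a fully seeded synthetic heterograft generator (two divergent
    genomes, tissue expression profiles, spiked mobile transcripts, paired-end
    reads with ground truth) so the whole pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    Rcpp,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    tools,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
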