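Package: ccs16s
Title: Curation, Denoising and Error Profiling for PacBio CCS 16S rRNA Amplicons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for curating circular consensus (CCS) 16S rRNA gene amplicon
    reads sequenced on long-read single-molecule platforms. Reads FASTQ in the
    PacBio dialect (quality zero encodes an ambiguous call), demultiplexes and
    orients reads against paired symmetric barcodes and degenerate primers,
    applies the basic homopolymer/length screen and the three error-correlated
    filters (barcode/primer mismatches, pass-count coverage, predicted error
    rate), measures true error rates and error-type spectra against mock
    community references, flags reference-based (in silico) chimeras, denoises
    with abundance-sorted pre-clustering at one difference per 100 nt, clusters
    OTUs by average neighbor at a 3% cutoff with closed-form rarefaction, and
    simulates mock-community CCS reads with a configurable error model so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    S4Vectors,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
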