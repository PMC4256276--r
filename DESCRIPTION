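Package: rigseq
Title: Insertion-Site Sequencing Analysis for Group II Intron Retrotransposition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of RIG-Seq libraries, a targeted
    amplicon-sequencing assay that maps group II intron retrotransposition
    events onto bacterial replicons. Provides a ground-truth synthetic read
    generator, barcode demultiplexing and intron-tag trimming to 15-16 nt
    genomic flanks, exact-match both-strand mapping against circular
    references, collapsing of mapped flanks into unique insertion events with
    relative frequencies, reservoir-subsampling normalization of unique-site
    counts, frequency-weighted insertion-site nucleotide profiles
    (C-6/T+5 statistics, consensus calls, information content), and sequence
    utilities for relaxase nick-site biochemistry (oligo arithmetic,
    in-silico PCR, primer-extension product lengths, oriT-similarity scans).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stringr,
    tibble,
    tidyr,
    withr
Suggests:
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
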