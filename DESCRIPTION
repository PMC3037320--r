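Package: wordclust
Title: Distance-Based Detection of Significant Clusters of DNA Words and
    Genomic Elements
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects statistically significant spatial clusters of DNA words
    (k-mers, including IUPAC-degenerate patterns) in FASTA sequences, or of
    arbitrary genomic elements supplied as BED intervals. Word copies are
    found by a greedy non-overlapping scan restricted to N-free contigs;
    distances between consecutive copies are compared with a geometric null
    to resolve a data-driven maximum-distance threshold (observed-distribution
    percentile, per-sequence or genome-wide observed/expected intersection,
    or a fixed distance); maximal runs of copies within the threshold are
    scored with a negative-binomial significance test. Also counts
    co-localization of clusters with gene regions (TSS, promoter window,
    UTRs, exons, introns) from refFlat annotation, and ships a synthetic-data
    simulator that plants clusters with known coordinates for benchmarking.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringi,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
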