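Package: utrapa
Title: 3'UTR Alternative Polyadenylation Isoforms from RNA-Seq Coverage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers, quantifies and compares alternative-polyadenylation
    (APA) 3'UTR isoforms of clustered gene families (such as mouse odorant
    receptor genes) from per-base RNA-Seq coverage. Builds genomic masks
    around target gene clusters, detects terminal-exon 3' ends by Poisson
    change-point segmentation of coverage downstream of the stop codon,
    merges ends within a precision window into polyA sites, scans for
    canonical and variant polyadenylation-signal hexamers, estimates
    per-isoform relative abundance by segment subtraction, classifies
    per-gene quantitative profiles, detects 3'UTR introns from splice
    junctions, and flags isoform conservation across datasets. Includes a
    ground-truthed synthetic-data generator so every stage is testable
    without sequencing data.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
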