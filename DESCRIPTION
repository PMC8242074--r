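Package: shallowcna
Title: Copy Number Alteration Profiling from Shallow Whole-Genome
    Sequencing of Microdissected Minibulk Samples
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers genome-wide copy number alteration (CNA) profiles from
    shallow (~0.1x) whole-genome sequencing of minute, morphologically
    uniform tissue samples. Reads are tabulated into fixed 1 Mb genomic
    bins, GC bias is removed by LOWESS regression, sample quality is
    gated on mapped-read count and the median absolute pairwise
    difference (MAPD), chromosomes are partitioned by a permutation-based
    circular binary segmentation, and per-sample genome complexity is
    summarised by a CNAscore combining segment-to-segment jumps with
    deviation from the sex-specific neutral ploidy. Cohort-level tools
    aggregate gain/loss calls into recurrence tracks, smallest common
    regions of recurrent CNAs, intra-patient pattern concordance, and
    diagnostic-support flags. A negative-binomial synthetic-data
    generator with known ground truth makes every stage testable without
    access to patient sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
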