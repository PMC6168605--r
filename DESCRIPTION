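Package: fequiv
Title: Functional-Equivalence Evaluation of Variant-Calling Pipelines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying how functionally equivalent two or more
    whole-genome sequencing processing pipelines are, given the variant
    callsets they produce from the same samples under a fixed variant
    caller. Implements pairwise and k-way concordance statistics for
    small variants (SNVs and indels), padded-breakpoint matching and a
    six-category classification for structural variants, an
    easy/medium/hard genome stratification, trio Mendelian-error rates
    stratified by concordance status, quality-by-concordance summaries,
    Phred quality-score binning, and a seeded synthetic multi-pipeline
    callset generator with which the whole evaluation can be exercised
    end to end without access to sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    IRanges,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    withr,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
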