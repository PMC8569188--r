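Package: clonebench
Title: Simulation and Benchmarking of Tumour Subclonal Deconvolution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates clonal tumour genomes on a reference sequence
    (germline and somatic SNVs, indels, copy-number events, aneuploidy and
    whole-genome duplication propagated down a clone tree), composes bulk
    tumour samples at chosen purity and depth with per-variant ground truth
    (cancer cell fractions, expected allele frequencies, mutated-copy
    multiplicities), and scores somatic point-mutation calls, allele-specific
    copy-number calls and cancer-cell-fraction estimates against that truth
    with precision-recall curves, binned copy-number agreement, the MADif
    statistic and the adjusted Rand index. Includes simple baselines
    (doubled VAFs, one-dimensional K-means) and seeded toy-data generators
    so the whole chain runs without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    readr,
    stats,
    utils,
    vcfR,
    Biostrings,
    IRanges,
    S4Vectors
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
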