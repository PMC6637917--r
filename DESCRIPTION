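Package: topoclust
Title: Supercoiling-Sensitive Gene and Cluster Analysis for Bacterial Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis of bacterial RNA-Seq responses to chromosome
    supercoiling imbalance. Provides upper-quartile count normalization,
    log2 fold-change based classification of supercoiling-sensitive genes
    with a nucleoid-associated-protein/topoisomerase exemption rule,
    sliding-window detection of supercoiling-sensitive gene clusters along
    a linear chromosome, densest-region search for hypersensitive regions,
    promoter AT-content profiling against random controls with positional
    significance tests, and comparative delta-delta-Ct qPCR quantification.
    A synthetic-data module simulates GC-rich linear genomes, operon-grouped
    annotations, negative-binomial replicate counts with spatially planted
    effects, promoter composition architecture, and Ct tables, so the whole
    pipeline is testable without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    rtracklayer,
    GenomicRanges,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
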