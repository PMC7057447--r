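Package: methylstates
Title: Methylation State Calling and Region Segmentation for Illumina
    BeadChip Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Calls un-, middle- and full-methylated states at single CpG
    sites measured on Illumina HM450K/EPIC methylation arrays using a
    two-layer two-state hidden Markov model with truncated-normal
    emissions, and segments the sparse probe grid into UMR/MMR/FMR
    genomic regions with CpG-island-aware gap merging.  Includes probe
    filtering and BED/TSV input-output, a synthetic methylome generator
    with known ground truth, evaluation utilities (base-pair overlap
    matrices between labeled region sets, common-site Pearson
    correlation, region-width summaries) and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    GenomicRanges,
    IRanges,
    jsonlite,
    methods,
    optparse,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
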