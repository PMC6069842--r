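Package: footprintbench
Title: Benchmarking Metrics for Transcription Factor Footprinting Pipelines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative evaluation of transcription-factor footprinting
    pipelines for chromatin accessibility assays (ATAC-seq, DNase1-seq).
    Provides replicate-reproducibility statistics over genomic bins
    (alignment and open-chromatin-region Pearson correlations, footprint
    overlap curves), ChIP-seq recovery measured as tie-aware ROC/AUC over
    motif sites, read-depth downsampling and saturation analysis with
    linear and power-law fits, a pipeline-configuration grid harness with
    AUC- and reproducibility-optimal selection, and a seeded simulator of
    ground-truth footprinting worlds so every metric is testable without
    external sequencing data. Interval arithmetic uses 0-based half-open
    (BED) coordinates throughout.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    IRanges,
    S4Vectors,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
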