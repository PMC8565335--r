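Package: epibind
Title: Predicting Epigenetic Events in New Cellular Contexts from
    Chromatin Accessibility
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts binary epigenetic events (transcription factor
    binding sites, histone modifications) in a query cellular context
    from its chromatin accessibility alone. Reference cell types with
    known ChIP-seq peaks are compared to the query through a locus-level
    chromatin accessibility similarity vector (CASV) computed over
    nested genomic windows, and their binarized peak calls are combined
    through per-cell-type neural network channels trained with a
    cell-type rotation scheme. Includes genome binning and peak
    binarization from BED/narrowPeak input, replicate consensus merging,
    multi-label imbalance-aware over- and undersampling, early stopping,
    seeded synthetic multi-cell-type fixture generation, and evaluation
    by area under the precision-recall curve and standardized partial
    AUC.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    GenomicRanges,
    IRanges,
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
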