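Package: epientropy
Title: Read-Level DNA Methylation Heterogeneity via Epiallele Entropy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies read-level DNA methylation heterogeneity from
    per-read CpG methylation calls. Counts epialleles over 4-mers of
    consecutive CpGs and computes normalized methylation entropy,
    reconstructs in-silico bulk samples from single-cell-derived clones
    by pooled epiallele resampling, measures coordination of methylation
    between CpG-island pairs phased on the same long read against a
    shuffle null, and calls hypermethylated CpG islands from per-CpG
    methylation rate tracks. Ships a synthetic-data generator emulating
    bimodal, disordered-intermediate, clonal and long-read phased
    methylation regimes so the whole analysis is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    data.table,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
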