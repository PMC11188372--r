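Package: MIEprofiler
Title: Dose-Response Profiling of Molecular Initiating Event Target Genes in
    Liver Transcriptomics
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for dose-response toxicogenomics of
    molecular initiating events (MIEs) in rodent liver: sample QC filtering,
    reads-per-million normalisation with pseudo-count log2 transform,
    replicate-outlier flagging, principal-component-regression extrapolation
    from a targeted gene panel to the whole transcriptome, per-dose one-way
    ANOVA differential expression with Benjamini-Hochberg FDR, transcription
    factor regulon ingestion in TRRUST dialect, per-MIE dysregulated-target
    profiling at a log2 fold-change threshold, sex- and chemical-class
    response-pattern classification, dose-trend detection, weighted-signature
    concordance, and network/heatmap export. Ships a synthetic-data generator
    that emulates a multi-chemical, multi-dose, two-sex rat study design with
    planted regulon-level effects, so every stage is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
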