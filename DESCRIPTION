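Package: poolscreen
Title: Pooled CRISPR Knockout Screen Analysis, Simulation, and Regulatory Integration
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of two-arm pooled CRISPR-Cas9 knockout screens in
    stem cells: fitness (dropout) screens read out over serial passages and
    FACS reporter-loss (enrichment) screens read out from a sorted cell
    fraction. Provides sgRNA library construction and I/O, a generative
    simulator of both screen arms with known ground truth, count-matrix QC
    (coverage, lost guides, inter-sample correlation), per-gene CRISPR
    Score computation with a non-targeting-control pseudo-gene empirical
    null and FDR-based essential/growth-restricting classification, ranked
    dual-screen intersection, and a rule-based regulatory-genomics layer
    (peak annotation, co-binding overlap, promoter/enhancer calling from
    ATAC and histone marks, and transcription-factor target-gene
    definition by multi-omics intersection).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    yaml,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: CRISPR, PooledScreens, FunctionalGenomics, Software
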