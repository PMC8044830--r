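Package: scarsTools
Title: Marker-Threshold Single-Cell Classification and Proximity
    Placement Enrichment for Stem Cell-Associated Retroviral Sequences
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying regulatory networks of stem
    cell-associated retroviral sequences (SCARS) in human preimplantation
    embryos and embryonic stem cells. Implements the multi-lineage
    markers expressing (MLME) cell classifier (median-exceedance
    expression calls gated by per-lineage marker thresholds, the
    pluripotency trio and telomerase), genome-wide proximity placement
    analysis (GPPA) associating genes to regulatory elements within a
    +/-10 kb window, hypergeometric/Fisher overlap enrichment with
    observed/expected ratios and combined scores, set-overlap accounting
    and prevalence-mortality attribution arithmetic, and seeded synthetic
    data generators with planted structure for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    rtracklayer,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: SingleCell, GeneSetEnrichment, GeneRegulation, Software
RoxygenNote: 7.3.3
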