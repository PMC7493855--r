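Package: IPMSelect
Title: Interactor Selection and Enrichment Analysis for IP-MS Interactome Studies
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for affinity-purification mass-spectrometry (IP-MS)
    interactome studies in which a bait pulldown is compared against an IgG
    control across replicate experiments. Implements a three-stage interactor
    filter (lineage/transcriptome presence, label-free-quantification
    enrichment over IgG, CRAPome-style contaminant flagging) with full
    stage-by-stage accounting, stage-resolved expression analysis (RPKM,
    dispersion-corrected differential expression on pooled counts, Venn
    partitioning, expression cross-tabulation, clustered heatmap matrices),
    hypergeometric gene-set over-representation with Benjamini-Hochberg
    correction, kappa-statistic term-similarity networks, a ground-truth
    synthetic-data generator for benchmarking every stage, and a single
    orchestrated pipeline producing machine-readable reports.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: Proteomics, MassSpectrometry, GeneSetEnrichment, Network, Software
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'IPMSelect-package.R'
    'enrichment.R'
    'expression.R'
    'filter.R'
    'pipeline.R'
    'simulate.R'
    'tables-io.R'
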