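Package: scExonScreen
Title: Downstream Analysis of Dual-Nuclease Single-Cell Exon-Deletion CRISPR Screens
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing pooled CRISPR exon-deletion screens with
    single-cell transcriptomic readouts, in which a hybrid guide RNA directs
    Cas9 and Cas12a to flanking introns to excise individual cassette exons.
    The package covers guide detection and per-cell perturbation assignment
    from dual-modality guide-capture matrices (including doublet and
    guide-decoupling removal), quality control and normalisation of the
    expression matrix, local perturbation-signature computation with
    mixture-model classification of perturbed versus escaping cells,
    pseudobulk negative-binomial differential expression with guides as
    replicates, cell-cycle phase scoring and dual-gate phase-enrichment
    testing, exon-versus-knockout phenotype divergence analysis, and
    annotation of targeted exons (frame preservation, inclusion/skipping
    isoforms, mutually exclusive exon substitution) from a GTF. A fully
    ground-truthed synthetic-data generator reproduces the statistical
    structure of such screens so that every stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    MASS,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    SingleCellExperiment,
    Biostrings,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    DESeq2
biocViews: CRISPR, SingleCell, DifferentialExpression, AlternativeSplicing,
    Transcriptomics, QualityControl
Config/testthat/edition: 3
RoxygenNote: 7.3.3
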