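Package: strandNO
Title: Nucleosome Occupancy and Structural-Variant Functional Analysis from Strand-seq
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Derives nucleosome-occupancy (NO) readouts from Strand-seq-style
    single-cell mono-nucleosomal fragment data and couples them with
    structural-variant subclone definitions to infer local
    (haplotype-specific) and global (clone-specific) changes in gene
    activity and pathway state. Provides fragment ingestion and QC,
    per-cell template-strand state classification, pseudobulk NO tracks
    and anchor-averaged profiles, gene-body NO count matrices with
    copy-number/library-size normalization, PLS-DA cell typing with
    VIP-based feature selection, a two-step differential gene-activity
    module (not-expressed gene filtering followed by negative-binomial
    GLM Wald tests or a PLS-DA/VIP permutation mode for low clonal
    frequencies), haplotype-specific tests around SV breakpoints
    (Wilcoxon, binomial LRT sliding windows with permutation adjustment,
    exact binomial tests at cis-regulatory elements, TAD-level
    Kolmogorov-Smirnov outlier tests), gene-set over-representation and
    pathway-level NO mixed-model tests, and a synthetic-data generator
    with full ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomeInfoDb,
    GenomicRanges,
    SummarizedExperiment,
    rtracklayer,
    lme4,
    glmnet,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    Rsamtools,
    mixOmics,
    DESeq2,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Epigenetics, SingleCell, StructuralVariation, Coverage, Software
RoxygenNote: 7.3.3
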