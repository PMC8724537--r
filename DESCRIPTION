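Package: GrowthOmics
Title: Multiomics Dissection of Quantitative Growth Traits in Tree Crops
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An integrated pipeline for dissecting quantitative growth
    traits (such as stem diameter in rubber tree) from multiomics data.
    Fits the multi-environment linear mixed model to extract genotype
    BLUPs, variance components and broad-sense heritability; performs
    genotype quality control, k-nearest-neighbour imputation, population
    structure and linkage-disequilibrium (LD) decay modelling; runs an
    iterative pseudo-QTN (FarmCPU-style) genome-wide association scan
    with permutation-based significance thresholds; expands association
    signals through LD; annotates markers with flanking transcripts;
    builds weighted (WGCNA-style) coexpression networks with topological
    overlap, UPGMA clustering, adaptive branch cutting and Kleinberg hub
    scoring of GWAS-seeded subnetworks; and models an Enzyme Commission
    (EC) metabolic network with centrality, degree-outlier hub calling
    and multi-resolution community detection. A synthetic-data module
    emulates the genotype, phenotype, expression and pathway inputs so
    the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    lme4,
    igraph,
    minpack.lm,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
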