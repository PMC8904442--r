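Package: mitomix
Title: Clonally Informative Mitochondrial Variants from Single-Cell Allele Counts
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies clonally informative mitochondrial DNA variants in
    single-cell RNA, DNA or ATAC sequencing data. For every candidate variant
    the alternative-allele counts across cells are fit with a one-component
    binomial model (a single shared heteroplasmy level) and a two-component
    binomial mixture (two heteroplasmy levels, indicating clonal structure);
    variants are ranked by the difference in Bayesian Information Criterion
    (deltaBIC) between the two models, and a selection cutoff is placed
    automatically at the knee of the cumulative deltaBIC curve. Includes a
    reader/writer for cellSNP-lite style sparse AD/DP matrices, a count-level
    clonal simulator with lineage trees and background noise, precision-recall
    and ROC benchmarking utilities, and a binomial-mixture EM clone-assignment
    stage for end-to-end clonal discovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    Matrix,
    S4Vectors,
    IRanges,
    SummarizedExperiment,
    Rcpp,
    jsonlite,
    vcfR,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    mclust,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: SingleCell, SNP, VariantDetection, Genetics, Software
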