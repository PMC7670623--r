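Package: methresp
Title: Blood DNA Methylation Analysis of Weight-Loss Intervention Response
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for array-based blood DNA methylation
    studies of lifestyle-intervention weight-loss response. Provides probe-level
    quality control (detection p-value filtering, cross-reactive and SNP probe
    flagging) and quantile normalization of beta values; reference-based
    leukocyte cell-type deconvolution with composition testing and adjustment;
    responder versus non-responder differentially methylated region (DMR)
    discovery using CpG clustering, binary segmentation and a two-dimensional
    Kolmogorov-Smirnov permutation test; single-CpG differential tests; an
    epigenome-wide association scan of baseline methylation against relative
    weight change combining Pearson and Spearman correlation; baseline
    methylation-score predictors of weight-loss success benchmarked by ROC
    analysis against an age/BMI linear score; chromatin-state annotation and
    probe-abundance-corrected gene-set enrichment. A synthetic-cohort generator
    with planted DMRs, weight-correlated CpGs and cell-type mixture structure
    makes every stage testable without access to protected patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    limma,
    pracma,
    data.table,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    jsonlite,
    rtracklayer,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: DNAMethylation, DifferentialMethylation, Epigenetics,
    MethylationArray, QualityControl, Normalization
RoxygenNote: 7.3.3
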