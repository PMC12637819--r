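Package: imqtl
Title: Cell Type-Interaction Methylation QTL Mapping from Bulk Tissue
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Maps cell type-interaction methylation quantitative trait loci
    (imQTLs) from bulk-tissue DNA methylation and genotype data. Provides
    reference-based cell-type deconvolution with a four-cell-type panel built
    from sorted-cell methylomes (robust partial correlation), genotype-by-cell
    type interaction models with stratified allele-frequency filtering and an
    effective-number-of-tests plus Bonferroni multiple-testing scheme,
    downstream classification of interaction effects (directional consistency,
    cell-type specificity, cross-cell-type sharing, replication), genomic
    annotation enrichment with random-effects meta-analysis, and approximate
    Bayes factor colocalization of interaction statistics with external
    summary statistics. A synthetic-data module generates genotypes, cell-type
    compositions, mixed methylomes with planted cell-type-specific effects,
    sorted-cell reference samples, and paired summary-statistic tracks with
    known ground truth, so every stage of the pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    limma,
    MASS,
    metafor,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
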