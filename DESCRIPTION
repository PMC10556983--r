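Package: qpcscan
Title: Detecting Non-Neutral Gene-Expression Divergence in Structured
    Selfing Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for testing whether constitutive and plastic components of
    gene expression measured in a two-site reciprocal transplant diverge beyond
    neutral expectation in a structured, highly selfing plant population. The
    core is a Q_PC scan: expression traits are projected onto principal
    components of the mean-centered (conditional) kinship matrix, additive
    genetic variance is estimated from minor ("neutral") PCs, and divergence
    along major axes of population structure is tested with F statistics and
    Storey q-values. Supporting tools cover genotype filtering and region
    masks, all-sites nucleotide diversity and absolute divergence (pixy-style
    comparison accounting), Weir-Cockerham FST over genomic windows and gene
    features, discriminant analysis of principal components (DAPC) for cluster
    inference and a transcriptome plasticity statistic, outgroup-polarized
    ancestral-allele bootstrap tests, Fisher enrichment, and a synthetic-data
    module that generates structured selfing genotypes, kinship-covariant
    traits and two-site count data with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
Suggests:
    DESeq2,
    MASS,
    mclust,
    optparse,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
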