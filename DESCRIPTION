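Package: assocnet
Title: Mixed-Model GWAS, Conditional Subgroup Scans and Trait-Locus
    Networks for Inbred Diversity Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An association-mapping pipeline for selfing-species diversity
    panels. Provides genotype QC (minor-allele-frequency and missingness
    filtering, k-nearest-neighbour imputation), simple-matching kinship,
    genotype principal components and dosage linkage disequilibrium; an
    EMMAX-style mixed-linear-model association scan with permutation-derived
    genome-wide thresholds; detection of significantly associated loci as
    LD-contiguous intervals around peak SNPs; a genotype-conditioned subgroup
    re-scan that uncovers epistatic and minor-effect loci; Inter-LD
    trait-locus association networks with pleiotropic key-node ranking and
    favourable-allele stacking curves; variance-weighted statistical power
    and FDR simulation over a QTN-by-heritability grid; and cross-environment
    BLUP of line performance by EM-REML. A synthetic-data module generates
    structured genotype panels and additive, epistatic and multi-environment
    traits so that the whole pipeline is testable without real data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    igraph,
    e1071,
    vcfR,
    withr
Suggests:
    lme4,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
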