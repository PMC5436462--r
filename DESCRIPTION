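Package: bfgm
Title: Functional Regression Tests for Gene-Gene Interaction Effects on
    RNA-Seq Read-Count Curves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tests for epistatic (gene-gene interaction) effects on gene
    expression measured by RNA-seq, treating the per-position read-count
    profile of a target gene as a function-valued trait and the genotype
    profiles of two gene regions as functional predictors.  Both sides are
    expanded in functional principal components and the interaction block of
    the resulting multivariate regression is tested with a Wald-type
    chi-square statistic (the BFGM test).  Includes the scalar-response
    comparator (SFGM), per-position and per-SNP-pair minimum-p comparators,
    regression on principal components, genotype quality control (singleton,
    duplicate and Hardy-Weinberg filters), median-of-ratios normalization,
    RPKM, the rank-based inverse normal transform, and a simulation engine
    for type-1 error and power studies under two-locus penetrance models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    MASS,
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
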