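Package: pedprs
Title: Pedigree-Aware Polygenic Risk, Heritability and Pleiotropy Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for dissecting the genetic architecture of a complex
    (mood-disorder-like) phenotype segregating in a single extended
    multigenerational pedigree. Provides pedigree validation and the recursive
    numerator relationship (kinship) matrix, REML linear mixed models for
    association and narrow-sense heritability with a kinship covariance kernel,
    polygenic risk scoring with allele harmonisation, LD clumping and p-value
    thresholding, LD-block-local risk scores with a Bonferroni-corrected
    block-wise association scan and cross-trait overlap reporting, a sibling
    polygenic transmission-disequilibrium test, genotype-based Mendelian
    disease calling with carrier-frequency tables and founder-enrichment
    filters, association-rule mining (support, confidence, lift) of
    disease/phenotype co-occurrence, and a fully seeded synthetic-data
    generator (pedigree growth, gene dropping with Haldane recombination,
    GWAS summary statistics, liability-threshold phenotypes, Mendelian
    variant injection) used to validate every stage end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
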