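Package: popdiff
Title: Genetic Diversity and Differentiation of Structured Populations from
    Sparse SNP Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end population-genetics analysis for small panels of
    biallelic SNPs genotyped across many populations: per-population allele
    frequencies, minor allele frequencies, observed and unbiased expected
    heterozygosity, Hardy-Weinberg chi-square tests, Wright's Fis,
    Weir-Cockerham theta (global and pairwise, with permutation significance
    and sequential Bonferroni correction), Nei's G_ST and standard genetic
    distance, agglomerative trees (UPGMA, complete linkage, Ward) with
    locus-bootstrap support and majority-rule consensus, PCA of genotypes and
    of distance matrices, and k-means clustering with silhouette and
    Davies-Bouldin model selection. Includes a synthetic genotype generator
    (per-population frequencies, inbreeding, Balding-Nichols differentiation)
    and reconstruction of genotype counts from published summary statistics,
    so the whole pipeline is testable without raw genotype data. Ships the
    published 11-population, 5-locus water-buffalo dairy-SNP panel as a
    frequency preset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    cluster,
    optparse,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
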