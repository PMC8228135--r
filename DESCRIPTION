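Package: canid
Title: Genomic Divergence and Inbreeding Analysis of Wolf-Like Dog Breeds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for SNP-array population genomics of dog breeds and wild
    canids: PLINK text and binary genotype input/output with marker
    harmonization and missingness quality control, runs-of-homozygosity
    detection by the consecutive-runs criterion with length-class binning and
    genomic inbreeding coefficients (F_ROH), Weir-Cockerham pairwise F_ST and
    Nei genetic distances, discriminant analysis of principal components
    (DAPC) with alpha-score model choice, maximum-likelihood admixture
    estimation with Evanno delta-K cluster selection, identity-by-state
    k-nearest-neighbour networks, candidate-gene-panel stratification by PCA
    and factor analysis, and a seeded synthetic-genotype generator
    (Balding-Nichols divergence, admixed cohorts, implanted autozygous
    tracts) for validating every stage against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    igraph,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    MASS
Config/testthat/edition: 3
RoxygenNote: 7.3.3
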