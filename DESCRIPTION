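Package: aquagp
Title: Genomic Prediction and SNP Panel Density Evaluation for
    Family-Structured Aquaculture Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genomic selection studies in aquaculture breeding
    populations composed of many full-sib and half-sib families. Implements
    a breeding-population simulator with linkage (Mendelian transmission
    under a Haldane recombination model), genotype quality control and
    LD-kNNi imputation, VanRaden genomic relationship matrices, pedigree
    numerator relationship matrices, KING-robust kinship with relationship
    degree classification, admixture-model clustering for marker-based
    pedigree reconstruction, single-kernel REML (GBLUP/PBLUP) heritability
    and breeding-value estimation, replicated k-fold cross-validation of
    predictive ability, and an orchestrated SNP-panel density downsampling
    experiment with Mantel comparisons of relationship matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    vcfR,
    vegan
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
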