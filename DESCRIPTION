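Package: domgblup
Title: Genomic Prediction with Locus-Specific Dominance Weights (CADM GBLUP)
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Genomic best linear unbiased prediction (GBLUP) with a combined
    additive-dominance relationship matrix (CADM) in which each locus's
    heterozygote code is weighted by an estimated degree of dominance, plus
    the classical additive-only (AM) and two-component additive + dominance
    (ADM) GBLUP models. Includes genotype and phenotype input handling with
    minor-allele-frequency filtering and least-squares fixed-effect
    correction, VanRaden additive and Vitezica dominance relationship
    matrices, an average-information REML engine with EM warm-up, Henderson
    mixed-model-equation prediction, k-fold cross-validation with
    training-only dominance weights, bootstrap model comparison with
    Bonferroni correction, and a configurable simulator of biallelic
    genotypes and traits with per-locus dominance degrees.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
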