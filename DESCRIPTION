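Package: wssgblup
Title: Weighted Single-Step Genomic BLUP for Genome-Wide Association
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Single-step genomic BLUP (ssGBLUP) and its iteratively weighted
    extension (WssGBLUP) for genome-wide association in livestock populations.
    Combines pedigree, genotype and phenotype information through the H matrix,
    predicts breeding values for continuous traits by direct mixed-model
    equations and for binary traits by a liability-threshold Gibbs sampler,
    back-solves SNP effects from genomic breeding values, reweights SNP
    variances over iterations, and reports the proportion of additive genetic
    variance explained by windows of adjacent SNPs. Includes genotype quality
    control, contemporary-group phenotype editing, and a gene-dropping
    simulator with planted QTL for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    stats,
    utils,
    methods,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
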