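Package: puregxe
Title: Pure Gene-Environment Interaction Scans for Quantitative Traits
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Two-step detection of pure gene-environment interactions in
    quantitative-trait genome-wide association studies. Main effects of an
    environmental factor and of each SNP are removed by stepwise projection
    pursuit regression residualization; the residuals are then scored with a
    partition-based influence measure (the I-score) on the joint genotype by
    environment partition, with significance assessed by permutation. Also
    provides two-means dichotomization of continuous covariates, age-stratified
    genotype-only scans, and an overlap analysis of top-SNP lists between
    subgroups combining FDR-based expected-true-positive estimation with a
    hypergeometric zero-overlap probability. A synthetic cohort generator with
    controllable main, pure-interaction, and age-regime-switching effects makes
    the whole pipeline testable without external genotype data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
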