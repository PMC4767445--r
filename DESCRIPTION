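Package: ltlmr
Title: Mendelian Randomization of Genotypically-Estimated Leukocyte
    Telomere Length in Case-Control Studies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A case-control analysis pipeline for Mendelian randomization
    of leukocyte telomere length (LTL) estimated from inherited genotype.
    Builds a weighted polygenic allele score from LTL-associated SNPs with
    per-allele effects in base pairs, applies sample- and SNP-level quality
    control (call rate, control-only Hardy-Weinberg equilibrium, imputation
    posterior-probability exclusion), and runs the downstream statistical
    battery: covariate-adjusted logistic regression for the score (per bp
    and per control-SD), septile-stratified odds ratios with a trend test,
    single-locus allelic tests, a binomial sign test of effect-direction
    concordance, and correlation of per-SNP variance explained. Includes a
    synthetic cohort generator matching the assumed genotype structure
    (unlinked autosomal biallelic SNPs in Hardy-Weinberg equilibrium,
    imputation-posterior uncertainty, ancestry and platform covariates) so
    the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml,
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
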