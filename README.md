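# ltlmr

Mendelian randomization of **genotypically-estimated leukocyte
telomere length (LTL)** in case-control studies, built around the
eight-SNP LTL instrument with per-allele effects expressed in base
pairs.

Directly measured LTL in cancer patients is confounded by age and
treatment and vulnerable to reverse causation.  Because genotype is
fixed at conception, a weighted allele score over LTL-associated SNPs,

&nbsp;&nbsp;&nbsp;&nbsp;*S<sub>j</sub>* = Σ<sub>i</sub> *w<sub>i</sub>* *g<sub>ij</sub>*,

with *g<sub>ij</sub>* the dosage of the "long" allele at SNP *i* and
*w<sub>i</sub>* its per-allele effect in bp, provides an instrument for
LTL whose case-control contrasts are free of those biases.  `ltlmr`
implements the full analysis pipeline for epidemiologists working with
such instruments:

* instrument handling: weights tables, VCF/dosage-matrix input,
  harmonization of alleles to long-allele dosage with strand-ambiguity
  protection;
* the study's QC filters (imputation posterior < 0.80, call rate
  < 98%, control-only HWE p < 0.001 — all strict exclusions);
* scoring (full 8-SNP and reduced 5-SNP instruments), control-defined
  septiles and per-control-SD standardization;
* the statistical battery: covariate-adjusted logistic regression for
  the score, septile ORs with trend and extreme contrasts,
  single-locus allelic tests, a binomial sign test of effect-direction
  concordance, and Cox-Snell/Pearson variance-explained correlation;
* a synthetic cohort generator (HWE genotypes at the instrument's
  control allele frequencies, additive logistic disease models,
  imputation-posterior noise, PC and platform covariates) so the whole
  pipeline is testable end to end without access to private genotype
  data.

## Worked example

Simulate a cohort at the study's scale (1130 cases, 6294 controls)
with each SNP's published per-allele glioma odds ratio, then run the
battery:

```r
library(ltlmr)

w  <- ltl_weights()          # the 8-SNP instrument; max_score(w) == 1215.6
co <- simulate_cohort(sim_config(1130, 6294, w,
                                 effect_mode = "per_snp_or",
                                 per_snp_or = w$glioma_or, seed = 2024))
scores <- score_cohort(co$genotypes, w, co$samples)

score_association(scores, co$samples)
#> mean score: cases 562.8 bp, controls 539.4 bp (diff 23.4 bp, 4.34%)
#> OR per SD = 1.194 (95% CI 1.119-1.273, p = 6.63e-08)

septile_association(scores, co$samples)
#>  septile    or ci_lo ci_hi        p
#>        1 0.607 0.468 0.786 0.000158
#>        ...
#>        7 1.219 0.977 1.521 0.080036
#> trend OR per septile = 1.098 (95% CI 1.063-1.134, p = 1.23e-08)

sign_test(single_locus_tests(co$genotypes, co$samples, w))
#> sign test (frequency mode): long allele more common in cases at 6 of 8 SNPs,
#> two-sided binomial p = 0.2891
```

The case-control score difference (23.4 bp, 4.3% of the control mean
here) fluctuates around its analytic expectation of 28.6 bp (5.3%)
across seeds; the control mean tracks the Hardy-Weinberg expectation
`score_moments(w)$mean` = 543.6 bp and the control SD its closed form
133.1 bp.  The per-septile odds ratios rise monotonically from the
bottom to the top septile, with the fourth septile as the reference.

`run_pipeline(pipeline_config(...))` performs QC → scoring →
association in one call and writes `qc_report.json`, `scores.tsv`,
`septile_boundaries.json`, `assoc_report.tsv` and `summary.json`.  A
thin command-line front end with `simulate`, `qc`, `score`,
`associate` and `report` subcommands is installed at
`system.file("cli", "ltlmr.R", package = "ltlmr")`.

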