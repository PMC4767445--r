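---
title: "Genotypically-estimated telomere length as a Mendelian randomization instrument"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotypically-estimated telomere length as a Mendelian randomization instrument}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ltlmr)
```

## The model

Leukocyte telomere length (LTL) measured directly in blood is entangled
with age, treatment history and reverse causation when compared between
cancer patients and controls.  `ltlmr` instead estimates *relative* LTL
from inherited genotype: a weighted allele score over eight unlinked
autosomal SNPs robustly associated with LTL in a large GWAS
meta-analysis.  For individual $j$ with long-allele dosage $g_{ij}$ at
SNP $i$ and per-allele effect $w_i$ (in base pairs of telomere repeat
length),

$$ S_j = \sum_{i=1}^{8} w_i\, g_{ij}. $$

Because the $g_{ij}$ are fixed at conception, case-control differences
in $S$ are not confounded by age, sex or therapy — the Mendelian
randomization argument.  The score ranges from 0 (no long alleles) to
twice the sum of the weights:

```{r}
w <- ltl_weights()
w
max_score(w)   # 1215.6 bp; an all-long vs all-short difference
```

The bundled instrument carries two allele-frequency columns: `eaf`
(from the LTL meta-analysis that produced the weights) and
`control_eaf` (among the glioma-study controls).  Analytic
expectations and the simulator use `control_eaf`, since the quantities
they target — the control score mean and SD, and the case-control
contrast — are properties of the control population:

```{r}
score_moments(w)   # HWE mean 543.6 bp, SD 133.1 bp
```

## Quality control

Three filters reproduce the study's semantics, all with *strict*
inequality exclusions:

* **Sample, imputation posterior** — a sample is excluded if its
  highest genotype-class posterior is `< 0.80` at any scored SNP
  (exactly 0.80 is retained), or if any scored genotype is missing.
* **SNP, call rate** — excluded if `< 0.98`.
* **SNP, Hardy-Weinberg** — excluded if the control-only HWE p-value is
  `< 0.001`.  HWE is evaluated on best-guess genotype classes (dosage
  rounded), because HWE is defined on classes, not on fractional
  dosages.  The default test is the Pearson chi-square with 1 df; an
  exact conditional test (`method = "exact"`) is available since the
  original choice of test is not documented.

SNP filters run first on all samples; sample filters then run on the
retained SNPs, mirroring an analysis in which array-level SNP QC
precedes analysis-specific sample exclusion.

## Scoring and stratification

Fractional (expected) dosages enter the score directly; the 0–16
long-allele count is a rounded display quantity only.  Imputed SNPs
are scored with expected dosage by default — the posterior-probability
exclusion already polices poorly imputed genotypes, and expected
dosage propagates the residual uncertainty rather than discarding it;
best-guess genotypes remain available by rounding upstream.

Septiles are defined among pooled controls and applied to cases.  The
quantile is the inverse-CDF order statistic (type 1, no
interpolation), chosen because it is reproducible bit-exactly; a score
equal to a boundary falls in the lower septile, and scores outside the
control range clamp to the extreme septiles.  Degenerate boundaries
(ties) are an error rather than a silent merge.  The per-SD exposure
divides by the pooled-control standard deviation (denominator
$n - 1$).

## Association battery

All fits are maximum-likelihood logistic regressions (IRLS, tolerance
$10^{-8}$, at most 50 iterations) adjusted for the first two ancestry
principal components and, when more than one platform is present, a
one-hot platform term.  Inference is Wald throughout (OR,
$\exp(\hat\beta \pm 1.96\,\mathrm{se})$, normal p), matching how such
studies report OR + CI + p.  Quasi-separation flags the fit and
suppresses the odds ratios instead of reporting them.

* **Score level**: OR per bp and per control-SD, plus case/control
  means and their percent difference (denominator: control mean).
* **Septiles**: indicator coding against the median (fourth) septile;
  a separate fit with integer septile 1..7 gives the trend OR ("per
  increasing septile"); the top-vs-bottom contrast is derived from the
  indicator fit's covariance.
* **Single locus**: one fit per SNP with long-allele dosage as the
  exposure, so OR > 1 means the long allele is more common in cases.
* **Sign test**: counts SNPs whose long allele is more common in
  cases and computes the two-sided binomial p,
  $p = \min\!\big(1, 2\min(P[X \le k], P[X \ge k])\big)$,
  $X \sim \mathrm{Bin}(n, 1/2)$.  The default compares raw allele
  frequencies ("observed more commonly in cases"); an adjusted-OR mode
  exists, and the two agree whenever all effect directions agree.
  Exact ties are dropped from $n$ with a warning.
* **Variance explained**: per SNP, the Cox-Snell pseudo-$R^2$
  $1 - (L_0/L_1)^{2/n}$ from an unadjusted single-SNP logistic fit of
  disease, and the Pearson $R^2$ from a linear fit of a continuous LTL
  phenotype; the two vectors are then correlated across SNPs.

## The synthetic cohort generator

No individual-level genotypes are distributed with studies of this
kind, so every downstream stage is exercised on simulated cohorts that
reproduce the structure the analysis assumes:

* genotypes at the eight SNPs drawn independently as
  $\mathrm{Binomial}(2, p_i)$ at the control allele frequencies —
  Hardy-Weinberg equilibrium with no linkage disequilibrium, matching
  instruments chosen on separate autosomes;
* case status from an additive logistic model, either per-SNP
  ($\mathrm{logit} = \alpha + \sum_i \log(\mathrm{OR}_i) g_i$) or
  score-mediated ($\alpha + \log(\mathrm{OR}_{SD}) S/\sigma_S$ with
  $\sigma_S$ the analytic control SD);
* the intercept $\alpha$ calibrated by bisection to a source-population
  prevalence of 0.15 — approximately the study's case fraction
  (1130/7424), which keeps rejection sampling efficient; because
  case-control sampling preserves additive logistic odds ratios, the
  recovery targets are insensitive to this choice;
* imputation uncertainty as soft GP triples: a genotype is emitted
  soft with probability `gp_frac`, its true class keeps $1-\epsilon$
  with $\epsilon \sim U(0, \texttt{gp\_noise})$, a homozygote leaks
  $2\epsilon/3$ to the adjacent heterozygote class and $\epsilon/3$
  beyond, and a heterozygote splits $\epsilon$ equally between the two
  homozygote classes (both neighbours are adjacent, so there is no
  preferred direction); this produces a controllable fraction of
  genotypes below the 0.80 exclusion threshold;
* PCs as standard normals independent of genotype; an optional
  `pc1_beta` couples PC1 to disease to verify that adjustment behaves;
* a continuous LTL phenotype `ltl_bp` = score + Gaussian noise
  (default SD 650 bp, a typical population SD of measured LTL, under
  which each SNP explains well under 1% of variance, as in real data).

What the generator does **not** emulate: linkage disequilibrium,
population stratification that correlates genotype with ancestry,
genotyping batch effects, pleiotropy (the simulated SNPs act on
disease only through the planted model), and age/sex structure.
Passing recovery tests therefore demonstrates that the estimators are
correct under the model's own assumptions, not that those assumptions
hold in any particular real cohort.

## Problem sizes and numerical choices

Parameter-recovery checks run at the study's scale — 1130 cases and
6294 controls — averaged over 25 seeded replicates, which makes the
Monte Carlo error on a recovered OR about 0.007; property-style checks
(CI coverage, HWE calibration) use 200–400 smaller replicates.  A
single global RNG is seeded from the configuration, so cohorts,
written files and the pipeline summary are byte-identical across
reruns.  Intercept calibration bisects over a fixed 100,000-draw Monte
Carlo sample of linear predictors and aborts if the intercept diverges
beyond ±50.

## Worked pipeline

```{r, eval = FALSE}
co  <- simulate_cohort(sim_config(1130, 6294, ltl_weights(),
                                  effect_mode = "score_or_per_sd",
                                  or_per_sd = 1.25, seed = 1))
out <- run_pipeline(pipeline_config(co$weights, co$genotypes,
                                    co$samples, "ltl_out"))
out$summary$or_per_sd
```

## Known limitations

* Strand-ambiguous (A/T, C/G) variants are refused unless the caller
  asserts forward-strand data; none of the bundled instrument's SNPs
  are ambiguous, but replacement instruments may be.
* The per-individual score extremes seen in any cohort are
  realizations, not model constants, and are not reproduced.
* No formal MR sensitivity analyses (MR-Egger, weighted median) are
  included; the instrument's robustness argument here is the
  reduced-score analysis, which recomputes the score without the
  TERC/TERT/RTEL1 loci (ceiling 644.4 bp) to show the association is
  not driven by loci with known pleiotropic potential.
* Cohort-level point estimates from the original private datasets are
  not exactly reproducible; the package targets the analytic
  quantities the instrument determines and recovery of planted
  parameters at matched sample sizes.
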