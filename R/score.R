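#' Genotypic LTL score in base pairs
#'
#' The score is the weighted sum over instrument SNPs of the long-LTL
#' allele dosage, each allele weighted by its per-allele effect in bp:
#' S = sum_i w_i g_i.  An individual with zero long alleles scores 0;
#' one homozygous long at every SNP scores twice the sum of the
#' weights.  Fractional (expected) dosages enter the sum directly;
#' `n_long_alleles` is a rounded display count.
#'
#' @param genotypes A `genotype_matrix` whose columns cover the
#'   instrument.
#' @param weights A `weights_table`.
#' @return A `score_table` data frame: `sample_id`, `score_bp`,
#'   `n_long_alleles`, `attrition_years` (score_bp divided by a nominal
#'   30 bp/year of age-related telomere loss), and `flagged` (TRUE when
#'   a dosage was missing; such samples get NA scores).
#' @export
compute_score <- function(genotypes, weights) {
  stopifnot(inherits(weights, "weights_table"))
  missing_snps <- setdiff(weights$rsid, colnames(genotypes$dosage))
  if (length(missing_snps) > 0L) {
    stop("genotypes lack instrument SNP(s): ",
         paste(missing_snps, collapse = ", "), call. = FALSE)
  }
  d <- genotypes$dosage[, weights$rsid, drop = FALSE]
  flagged <- apply(is.na(d), 1, any)
  s <- as.vector(d %*% weights$bp_weight)
  n_long <- as.vector(round(d) %*% rep(1, ncol(d)))
  s[flagged] <- NA_real_
  n_long[flagged] <- NA_real_
  out <- data.frame(sample_id = rownames(d), score_bp = s,
                    n_long_alleles = n_long,
                    attrition_years = s / 30,
                    flagged = flagged, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("score_table", "data.frame")
  out
}

#' Score on a reduced instrument excluding named genes
#'
#' Recomputes the score after dropping the SNPs of the listed genes;
#' used to test whether an association survives removal of loci with
#' known pleiotropic potential (by default the telomerase and helicase
#' loci TERC, TERT and RTEL1, leaving the five-SNP instrument whose
#' ceiling is 644.4 bp).
#'
#' @inheritParams compute_score
#' @param exclude_genes Character vector of gene labels to drop; must
#'   be a subset of the instrument's genes and must not empty it.
#' @return A `score_table` (see [compute_score()]).
#' @export
reduced_score <- function(genotypes, weights,
                          exclude_genes = c("TERC", "TERT", "RTEL1")) {
  stopifnot(inherits(weights, "weights_table"))
  unknown <- setdiff(exclude_genes, weights$gene)
  if (length(unknown) > 0L) {
    stop("exclude_genes not in instrument: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  kept <- weights[!weights$gene %in% exclude_genes, , drop = FALSE]
  if (nrow(kept) == 0L) {
    stop("exclusion set empties the instrument", call. = FALSE)
  }
  class(kept) <- class(weights)
  compute_score(genotypes, kept)
}

#' Septile boundaries from control scores
#'
#' Boundaries are the k/7 empirical quantiles of the control score
#' distribution for k = 1..6, using the inverse-CDF order-statistic
#' quantile (type 1, no interpolation).
#'
#' @param control_scores Numeric vector of control scores.
#' @param n_quantiles Number of strata (default 7).
#' @return Numeric vector of `n_quantiles - 1` boundaries.
#' @export
septile_boundaries <- function(control_scores, n_quantiles = 7L) {
  control_scores <- control_scores[!is.na(control_scores)]
  if (length(control_scores) < n_quantiles) {
    stop("fewer controls than septiles", call. = FALSE)
  }
  b <- unname(stats::quantile(control_scores,
                              probs = seq_len(n_quantiles - 1) / n_quantiles,
                              type = 1))
  if (any(diff(b) <= 0)) {
    stop("degenerate septile boundaries (ties in control scores)",
         call. = FALSE)
  }
  b
}

#' Assign control-defined septiles to all samples
#'
#' Boundaries are computed among controls only and applied to cases
#' and controls alike.  A score equal to a boundary falls in the lower
#' septile; scores below the lowest control score clamp to septile 1
#' and above the highest to the top septile.
#'
#' @param scores A `score_table`.
#' @param samples A `sample_table` aligned by `sample_id`.
#' @param n_quantiles Number of strata (default 7).
#' @return The `score_table` with a `septile` column (integer 1..7);
#'   boundaries attached as attribute `"boundaries"`.
#' @export
assign_septiles <- function(scores, samples, n_quantiles = 7L) {
  stopifnot(inherits(scores, "score_table"))
  st <- samples$status[match(scores$sample_id, samples$sample_id)]
  b <- septile_boundaries(scores$score_bp[st == 0], n_quantiles)
  scores$septile <- vapply(scores$score_bp, function(s) {
    if (is.na(s)) NA_integer_ else 1L + sum(b < s)
  }, integer(1))
  attr(scores, "boundaries") <- b
  scores
}

#' Standardize scores to control SD units
#'
#' Subtracts the pooled-control mean and divides by the pooled-control
#' standard deviation (denominator n - 1), so the per-SD odds ratio is
#' interpretable as risk per one control-SD of genotypic LTL.
#'
#' @inheritParams assign_septiles
#' @return The `score_table` with a `score_sd_units` column; control
#'   mean and SD attached as attributes `"control_mean"` and
#'   `"control_sd"`.
#' @export
standardize <- function(scores, samples) {
  stopifnot(inherits(scores, "score_table"))
  st <- samples$status[match(scores$sample_id, samples$sample_id)]
  ctrl <- scores$score_bp[st == 0 & !is.na(scores$score_bp)]
  if (length(ctrl) < 2L) stop("need at least 2 controls", call. = FALSE)
  m <- mean(ctrl); s <- stats::sd(ctrl)
  if (s == 0) stop("zero control SD; scores degenerate", call. = FALSE)
  scores$score_sd_units <- (scores$score_bp - m) / s
  attr(scores, "control_mean") <- m
  attr(scores, "control_sd") <- s
  scores
}

#' Score, standardize and stratify in one call
#'
#' Convenience wrapper: [compute_score()], then [standardize()] and
#' [assign_septiles()] using control-defined moments and boundaries.
#'
#' @inheritParams compute_score
#' @param samples A `sample_table`.
#' @param n_quantiles Number of strata (default 7).
#' @return A `score_table` with columns `score_bp`, `n_long_alleles`,
#'   `score_sd_units`, `septile`.
#' @export
score_cohort <- function(genotypes, weights, samples, n_quantiles = 7L) {
  s <- compute_score(genotypes, weights)
  s <- standardize(s, samples)
  assign_septiles(s, samples, n_quantiles)
}
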