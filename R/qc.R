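#' Hardy-Weinberg equilibrium test from genotype counts
#'
#' Default is the Pearson chi-square goodness-of-fit test with 1 df:
#' expected counts n*(p^2, 2pq, q^2) at the sample allele frequency
#' p = (2 n_AA + n_Aa) / 2n.  `method = "exact"` gives the exact
#' conditional test: given the observed allele counts, the probability
#' of each heterozygote count is computed from the multinomial HWE
#' likelihood (which is independent of p after conditioning), and the
#' two-sided p-value sums the probabilities of all outcomes no more
#' likely than the observed one.
#'
#' @param n_AA,n_Aa,n_aa Genotype counts (AA = two effect alleles).
#' @param method `"chisq"` or `"exact"`.
#' @return List with `p` in \[0, 1\], `chisq` (NA for exact mode) and
#'   `monomorphic` flag.  Monomorphic SNPs return p = 1 by convention.
#' @export
hwe_test <- function(n_AA, n_Aa, n_aa, method = c("chisq", "exact")) {
  method <- match.arg(method)
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  n <- n_AA + n_Aa + n_aa
  if (n <= 0) stop("total genotype count must be positive", call. = FALSE)
  nA <- 2 * n_AA + n_Aa
  if (nA == 0 || nA == 2 * n) {
    return(list(p = 1.0, chisq = if (method == "chisq") 0 else NA_real_,
                monomorphic = TRUE))
  }
  if (method == "chisq") {
    p_hat <- nA / (2 * n)
    expected <- n * c(p_hat^2, 2 * p_hat * (1 - p_hat), (1 - p_hat)^2)
    chisq <- sum((c(n_AA, n_Aa, n_aa) - expected)^2 / expected)
    list(p = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
         chisq = chisq, monomorphic = FALSE)
  } else {
    list(p = hwe_exact_p(n_AA, n_Aa, n_aa), chisq = NA_real_,
         monomorphic = FALSE)
  }
}

# Exact conditional HWE p-value via log-factorial closed form:
# P(n_Aa | n, nA) = n! nA! na! 2^n_Aa / (n_AA! n_Aa! n_aa! (2n)!).
hwe_exact_p <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n - nA
  # heterozygote count has the parity of nA and range [max parity, min(nA, na)]
  het <- seq(nA %% 2, min(nA, na), by = 2)
  logp <- lfactorial(n) + lfactorial(nA) + lfactorial(na) +
    het * log(2) - lfactorial((nA - het) / 2) - lfactorial(het) -
    lfactorial((na - het) / 2) - lfactorial(2 * n)
  p <- exp(logp - max(logp)); p <- p / sum(p)
  obs <- p[match(n_Aa, het)]
  min(1, sum(p[p <= obs * (1 + 1e-12)]))
}

# Best-guess genotype counts (AA/Aa/aa in effect-allele copies) from a
# dosage vector; NA dropped.
dosage_genotype_counts <- function(d) {
  g <- round(d[!is.na(d)])
  c(n_AA = sum(g == 2), n_Aa = sum(g == 1), n_aa = sum(g == 0))
}

#' SNP-level quality-control filter
#'
#' A SNP is retained iff its call rate is at least `call_rate_min` and
#' its Hardy-Weinberg p-value among controls is at least `hwe_min_p`
#' (both strict-inequality exclusions: a SNP exactly at a threshold is
#' retained).  HWE uses best-guess genotypes (dosage rounded to the
#' nearest class), computed on controls only.  Removing instrument
#' SNPs is reported with a warning, not fatal.
#'
#' @param genotypes A `genotype_matrix`.
#' @param samples A `sample_table` aligned by sample ID.
#' @param call_rate_min Minimum call rate (default 0.98).
#' @param hwe_min_p Minimum control HWE p-value (default 0.001).
#' @param hwe_method Passed to [hwe_test()].
#' @return List with `retained` (rsIDs) and `snp_report` (data frame of
#'   per-SNP call rate, control HWE p, retained flag, reason).
#' @export
filter_snps <- function(genotypes, samples, call_rate_min = 0.98,
                        hwe_min_p = 0.001, hwe_method = "chisq") {
  stopifnot(call_rate_min >= 0, call_rate_min <= 1,
            hwe_min_p >= 0, hwe_min_p <= 1)
  d <- genotypes$dosage
  controls <- samples$sample_id[samples$status == 0]
  if (length(controls) == 0L) {
    stop("control subset is empty; control-only HWE undefined",
         call. = FALSE)
  }
  call_rate <- colMeans(!is.na(d))
  hwe_p <- vapply(colnames(d), function(snp) {
    cnt <- dosage_genotype_counts(d[controls, snp])
    hwe_test(cnt["n_AA"], cnt["n_Aa"], cnt["n_aa"],
             method = hwe_method)$p
  }, numeric(1))
  ok_cr <- call_rate >= call_rate_min
  ok_hwe <- hwe_p >= hwe_min_p
  reason <- rep("", ncol(d))
  reason[!ok_cr] <- "call_rate"
  reason[ok_cr & !ok_hwe] <- "hwe"
  retained <- colnames(d)[ok_cr & ok_hwe]
  if (length(retained) < ncol(d)) {
    warning("instrument SNP(s) removed by QC: ",
            paste(setdiff(colnames(d), retained), collapse = ", "),
            "; score proceeds on the remainder", call. = FALSE)
  }
  list(retained = retained,
       snp_report = data.frame(rsid = colnames(d),
                               call_rate = unname(call_rate),
                               hwe_p_controls = unname(hwe_p),
                               retained = ok_cr & ok_hwe,
                               reason = reason,
                               stringsAsFactors = FALSE))
}

#' Sample-level quality-control filter
#'
#' A sample is excluded if its maximum imputation posterior probability
#' is below `gp_threshold` at any scored SNP (strict: exactly 0.80 is
#' retained), or if any scored genotype is missing.  Each exclusion
#' carries one primary reason (low GP checked first).
#'
#' @param genotypes A `genotype_matrix` (already restricted to scored
#'   SNPs).
#' @param samples A `sample_table`.
#' @param gp_threshold Minimum acceptable per-genotype posterior
#'   (default 0.80).
#' @return List with `retained` (sample IDs) and `sample_report` (data
#'   frame of excluded samples with reasons).
#' @export
filter_samples <- function(genotypes, samples, gp_threshold = 0.80) {
  stopifnot(gp_threshold >= 0, gp_threshold <= 1)
  d <- genotypes$dosage
  gpm <- genotypes$gp_max
  low_gp <- apply(gpm < gp_threshold, 1, any)
  has_missing <- apply(is.na(d), 1, any)
  excluded <- low_gp | has_missing
  reason <- ifelse(low_gp, "gp_below_threshold", "missing_genotype")
  if (all(excluded)) {
    stop("all samples excluded by QC (empty analysis set)", call. = FALSE)
  }
  list(retained = rownames(d)[!excluded],
       sample_report = data.frame(
         sample_id = rownames(d)[excluded],
         reason = reason[excluded],
         stringsAsFactors = FALSE))
}

#' Apply the full QC stage
#'
#' SNP filters are computed first on all samples; sample filters then
#' run on the retained SNPs only.  Returns filtered data plus a
#' `qc_report`.
#'
#' @inheritParams filter_snps
#' @inheritParams filter_samples
#' @return List with `genotypes` (filtered `genotype_matrix`),
#'   `samples` (filtered `sample_table`) and `report` (a `qc_report`).
#' @export
run_qc <- function(genotypes, samples, gp_threshold = 0.80,
                   call_rate_min = 0.98, hwe_min_p = 0.001,
                   hwe_method = "chisq") {
  stopifnot(setequal(rownames(genotypes$dosage), samples$sample_id))
  d <- genotypes$dosage[samples$sample_id, , drop = FALSE]
  gpm <- genotypes$gp_max[samples$sample_id, , drop = FALSE]
  genotypes <- genotype_matrix(d, gpm, source = unname(genotypes$source))

  snp_f <- filter_snps(genotypes, samples, call_rate_min, hwe_min_p,
                       hwe_method)
  g2 <- genotype_matrix(
    genotypes$dosage[, snp_f$retained, drop = FALSE],
    genotypes$gp_max[, snp_f$retained, drop = FALSE],
    source = unname(genotypes$source[snp_f$retained]))
  sample_f <- filter_samples(g2, samples, gp_threshold)
  g3 <- genotype_matrix(
    g2$dosage[sample_f$retained, , drop = FALSE],
    g2$gp_max[sample_f$retained, , drop = FALSE],
    source = unname(g2$source))
  s3 <- samples[samples$sample_id %in% sample_f$retained, , drop = FALSE]
  class(s3) <- class(samples)

  report <- structure(list(
    n_samples_in = nrow(samples), n_samples_out = nrow(s3),
    n_snps_in = ncol(genotypes$dosage), n_snps_out = ncol(g3$dosage),
    snp_report = snp_f$snp_report,
    excluded_samples = sample_f$sample_report,
    thresholds = list(gp_threshold = gp_threshold,
                      call_rate_min = call_rate_min,
                      hwe_min_p = hwe_min_p, hwe_method = hwe_method)),
    class = "qc_report")
  list(genotypes = g3, samples = s3, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("QC: samples %d -> %d, SNPs %d -> %d\n",
              x$n_samples_in, x$n_samples_out,
              x$n_snps_in, x$n_snps_out))
  cat(sprintf("thresholds: gp >= %.2f, call rate >= %.2f, control HWE p >= %g (%s)\n",
              x$thresholds$gp_threshold, x$thresholds$call_rate_min,
              x$thresholds$hwe_min_p, x$thresholds$hwe_method))
  dropped <- x$snp_report[!x$snp_report$retained, , drop = FALSE]
  if (nrow(dropped) > 0L) {
    cat("dropped SNPs:\n"); print(dropped, row.names = FALSE)
  }
  invisible(x)
}
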