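# Shared fixtures and independent oracles, all built in code.

# A three-SNP toy instrument with unambiguous alleles.
toy_weights <- function() {
  as_weights_table(data.frame(
    rsid = c("rs1", "rs2", "rs3"),
    chrom = c("1", "2", "3"),
    gene = c("G1", "G2", "G3"),
    effect_allele = c("C", "G", "A"),
    eaf = c(0.3, 0.5, 0.8),
    beta_ratio = c(0.05, 0.06, 0.07),
    bp_weight = c(10, 20, 40),
    stringsAsFactors = FALSE))
}

toy_samples <- function(status, ids = sprintf("S%03d", seq_along(status))) {
  as_sample_table(data.frame(
    sample_id = ids, status = status,
    pc1 = 0, pc2 = 0,
    platform = "illumina", cohort = "toy",
    stringsAsFactors = FALSE))
}

toy_genotypes <- function(dosage_by_sample, snps) {
  m <- do.call(rbind, dosage_by_sample)
  colnames(m) <- snps
  if (is.null(rownames(m))) {
    rownames(m) <- sprintf("S%03d", seq_len(nrow(m)))
  }
  genotype_matrix(m)
}

# Exact HWE oracle: enumerate every genotype configuration with the
# observed total and allele count, weight by the multinomial HWE
# likelihood at an arbitrary interior allele frequency (the
# conditional distribution does not depend on it), and sum the
# probabilities of configurations no more likely than the observed.
hwe_exact_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  p <- 0.3
  probs <- c(p^2, 2 * p * (1 - p), (1 - p)^2)
  configs <- list()
  for (aa in 0:n) for (ab in 0:(n - aa)) {
    bb <- n - aa - ab
    if (2 * aa + ab == nA) {
      configs[[length(configs) + 1L]] <-
        c(aa = aa, ab = ab, bb = bb,
          pr = stats::dmultinom(c(aa, ab, bb), prob = probs))
    }
  }
  m <- do.call(rbind, configs)
  m[, "pr"] <- m[, "pr"] / sum(m[, "pr"])
  obs <- m[m[, "aa"] == n_AA & m[, "ab"] == n_Aa, "pr"]
  min(1, sum(m[m[, "pr"] <= obs * (1 + 1e-12), "pr"]))
}

# Brute-force score oracle: accumulate the score one allele (scalar
# multiply-add) at a time, per sample and SNP.
score_oracle <- function(dosage, weights) {
  out <- numeric(nrow(dosage))
  for (i in seq_len(nrow(dosage))) {
    s <- 0
    for (k in seq_len(ncol(dosage))) {
      s <- s + weights$bp_weight[match(colnames(dosage)[k],
                                       weights$rsid)] * dosage[i, k]
    }
    out[i] <- s
  }
  out
}

# Small simulated cohort for integration-style tests.
small_cohort <- function(seed = 11, n_cases = 150, n_controls = 600, ...) {
  simulate_cohort(sim_config(n_cases, n_controls, ltl_weights(),
                             seed = seed, ...))
}
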