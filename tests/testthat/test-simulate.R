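test_that("config validation rejects impossible settings", {
  w <- ltl_weights()
  expect_error(sim_config(0, 10, w), "positive")
  expect_error(sim_config(10, 10, w, baseline_prevalence = 1.2), "0, 1")
  expect_error(sim_config(10, 10, w, missing_rate = -0.1), "rates")
  expect_error(sim_config(10, 10, w, effect_mode = "per_snp_or"),
               "per_snp_or")
  expect_error(sim_config(10, 10, w, effect_mode = "score_or_per_sd",
                          or_per_sd = -1), "positive odds ratio")
})

test_that("genotypes follow Hardy-Weinberg proportions at the configured frequency", {
  set.seed(2)
  w <- as_weights_table(data.frame(
    rsid = c("a1", "a2"), chrom = c("1", "2"), gene = c("X", "Y"),
    effect_allele = c("C", "G"), eaf = c(0.5, 0.01),
    beta_ratio = 0.1, bp_weight = 10))
  n <- 200000
  g <- simulate_genotypes(n, w)
  # heterozygote fraction at p = 0.5 is 0.5; 3 binomial SEs
  se <- sqrt(0.5 * 0.5 / n)
  expect_lt(abs(mean(g[, 1] == 1) - 0.5), 3 * se)
  # homozygous-effect fraction at p = 0.01 is p^2 = 1e-4
  se2 <- sqrt(1e-4 * (1 - 1e-4) / n)
  expect_lt(abs(mean(g[, 2] == 2) - 1e-4), 3 * se2)
})

test_that("control allele frequencies are recovered within 3 binomial SEs", {
  co <- small_cohort(seed = 31, n_cases = 100, n_controls = 2000)
  w <- co$weights
  ctrl <- co$samples$sample_id[co$samples$status == 0]
  for (k in seq_len(nrow(w))) {
    obs <- mean(co$genotypes$dosage[ctrl, w$rsid[k]]) / 2
    p <- w$control_eaf[k]
    se <- sqrt(p * (1 - p) / (2 * length(ctrl)))
    expect_lt(abs(obs - p), 3.5 * se, label = w$rsid[k])
  }
})

test_that("hard-call cohorts carry unit posteriors and soft ones do not", {
  co <- small_cohort(seed = 41, n_cases = 50, n_controls = 200)
  expect_true(all(co$genotypes$gp_max == 1))
  expect_null(co$gp)
  co2 <- small_cohort(seed = 41, n_cases = 50, n_controls = 200,
                      gp_frac = 0.5, gp_noise = 0.4)
  expect_true(any(co2$genotypes$gp_max < 1))
  expect_true(all(co2$genotypes$gp_max >= 0.6 - 1e-12))
  soft <- !is.na(co2$gp[, , 1])
  sums <- co2$gp[, , 1] + co2$gp[, , 2] + co2$gp[, , 3]
  expect_equal(unname(sums[soft]), rep(1, sum(soft)))
})

test_that("cohort sampling honors quotas, labels and determinism", {
  cfg <- sim_config(1, 1, ltl_weights(), seed = 8)
  co <- simulate_cohort(cfg)
  expect_equal(nrow(co$samples), 2L)
  expect_equal(sum(co$samples$status), 1L)

  co_a <- small_cohort(seed = 77, gp_frac = 0.2, gp_noise = 0.3,
                       missing_rate = 0.01)
  co_b <- small_cohort(seed = 77, gp_frac = 0.2, gp_noise = 0.3,
                       missing_rate = 0.01)
  expect_identical(co_a$genotypes$dosage, co_b$genotypes$dosage)
  expect_identical(co_a$samples, co_b$samples)

  dir_a <- withr::local_tempdir(); dir_b <- withr::local_tempdir()
  fa <- write_cohort(co_a, dir_a); fb <- write_cohort(co_b, dir_b)
  for (f in names(fa)) {
    expect_identical(readLines(fa[[f]]), readLines(fb[[f]]),
                     label = f)
  }
})

test_that("written cohorts round-trip through VCF, sample TSV and truth JSON", {
  co <- small_cohort(seed = 13, n_cases = 40, n_controls = 160,
                     gp_frac = 0.3, gp_noise = 0.3,
                     effect_mode = "score_or_per_sd", or_per_sd = 1.25)
  out <- withr::local_tempdir()
  files <- write_cohort(co, out)
  g2 <- read_vcf_genotypes(files[["vcf"]], co$weights)
  expect_equal(g2$dosage, co$genotypes$dosage, tolerance = 1e-3)
  expect_equal(g2$gp_max, co$genotypes$gp_max, tolerance = 1e-3)
  s2 <- read_samples(files[["samples"]])
  expect_equal(s2$status, co$samples$status)
  truth <- jsonlite::read_json(files[["truth"]], simplifyVector = TRUE)
  expect_equal(truth$or_per_sd, 1.25)
  expect_equal(truth$effect_mode, "score_or_per_sd")
  expect_equal(truth$seed, 13)
})

test_that("null cohorts show no score-disease association", {
  co <- simulate_cohort(sim_config(800, 3000, ltl_weights(),
                                   effect_mode = "null", seed = 19))
  scores <- score_cohort(co$genotypes, co$weights, co$samples)
  sa <- score_association(scores, co$samples)
  expect_lt(abs(sa$per_sd$or - 1), 0.12)
  expect_lt(abs(sa$diff_bp), 20)
})

test_that("the case-control score shift matches the small-effect analytic oracle", {
  w <- ltl_weights()
  p <- w$control_eaf
  oracle <- sum(w$bp_weight * 2 * p * (1 - p) * log(w$glioma_or))
  expect_equal(oracle, 28.6, tolerance = 0.005)
  co <- simulate_cohort(sim_config(12000, 12000, w,
                                   effect_mode = "per_snp_or",
                                   per_snp_or = w$glioma_or, seed = 23))
  st <- co$samples$status
  s <- as.vector(co$genotypes$dosage %*% w$bp_weight)
  diff <- mean(s[st == 1]) - mean(s[st == 0])
  # analytic SD of the difference of means ~ sqrt(2) * 133 / sqrt(12000)
  expect_lt(abs(diff - oracle), 3 * sqrt(2) * 133.1 / sqrt(12000))
})

test_that("a planted per-SD odds ratio is recovered by the fitted model", {
  co <- simulate_cohort(sim_config(1130, 6294, ltl_weights(),
                                   effect_mode = "score_or_per_sd",
                                   or_per_sd = 1.25, seed = 29))
  scores <- score_cohort(co$genotypes, co$weights, co$samples)
  sa <- score_association(scores, co$samples)
  expect_gt(sa$per_sd$ci_hi, 1.25)
  expect_lt(sa$per_sd$ci_lo, 1.25)
})

test_that("confounded mode biases the crude fit and PC adjustment removes it", {
  co <- simulate_cohort(sim_config(1500, 4500, ltl_weights(),
                                   effect_mode = "null",
                                   pc1_beta = 1.0, seed = 37))
  scores <- score_cohort(co$genotypes, co$weights, co$samples)
  adj <- score_association(scores, co$samples)
  expect_lt(abs(adj$per_sd$or - 1), 0.1)
  # the adjusted fit must place pc1 as a strong term
  pc1_row <- adj$fit_per_sd$terms[adj$fit_per_sd$terms$term == "pc1", ]
  expect_lt(pc1_row$p, 1e-10)
  expect_equal(pc1_row$estimate, 1.0, tolerance = 0.15)
})
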