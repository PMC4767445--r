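test_that("logistic fit reproduces the closed-form 2x2 odds ratio", {
  # contingency counts: exposed cases a, unexposed cases b,
  # exposed controls c, unexposed controls d
  cases <- list(c(a = 40, b = 60, c = 25, d = 75),
                c(a = 10, b = 15, c = 30, d = 5),
                c(a = 120, b = 80, c = 60, d = 140))
  for (cc in cases) {
    y <- c(rep(1, cc["a"] + cc["b"]), rep(0, cc["c"] + cc["d"]))
    x <- c(rep(1, cc["a"]), rep(0, cc["b"]),
           rep(1, cc["c"]), rep(0, cc["d"]))
    fit <- fit_logistic(y, data.frame(x = x))
    r <- fit$terms[fit$terms$term == "x", ]
    or_hand <- (cc["a"] * cc["d"]) / (cc["b"] * cc["c"])
    se_woolf <- sqrt(sum(1 / cc))
    expect_equal(r$or, unname(or_hand), tolerance = 1e-6)
    expect_equal(r$se, unname(se_woolf), tolerance = 1e-6)
    expect_equal(r$ci_lo, unname(exp(log(or_hand) - 1.96 * se_woolf)),
                 tolerance = 1e-5)
  }
})

test_that("degenerate designs are rejected or flagged", {
  expect_error(fit_logistic(rep(1, 10), data.frame(x = rnorm(10))),
               "at least one case")
  y <- rep(c(0, 1), 20)
  expect_error(fit_logistic(y, data.frame(x = 1:40, x2 = 2 * (1:40))),
               "collinear")
  # complete separation: flagged, no odds ratio reported
  fit <- suppressWarnings(fit_logistic(y, data.frame(x = y * 2 - 1)))
  expect_false(fit$converged)
  expect_true(all(is.na(fit$terms$or)))
})

test_that("flipping the exposure allele inverts the odds ratio exactly", {
  co <- small_cohort(seed = 71, n_cases = 120, n_controls = 400)
  d <- co$genotypes$dosage[, "rs2736100"]
  st <- co$samples$status
  f1 <- fit_logistic(st, data.frame(dosage = d))
  f2 <- fit_logistic(st, data.frame(dosage = 2 - d))
  r1 <- f1$terms[f1$terms$term == "dosage", ]
  r2 <- f2$terms[f2$terms$term == "dosage", ]
  expect_equal(r1$or, 1 / r2$or, tolerance = 1e-8)
  expect_equal(r1$p, r2$p, tolerance = 1e-8)
})

test_that("Wald CIs cover planted effects at the nominal rate", {
  set.seed(81)
  beta <- log(1.5)
  reps <- 200L
  covered <- 0L
  for (r in seq_len(reps)) {
    g <- rbinom(600, 2, 0.4)
    y <- rbinom(600, 1, plogis(-1 + beta * g))
    fit <- fit_logistic(y, data.frame(g = g))
    row <- fit$terms[fit$terms$term == "g", ]
    if (row$ci_lo <= exp(beta) && exp(beta) <= row$ci_hi) {
      covered <- covered + 1L
    }
  }
  # 3 Monte Carlo SEs around 0.95
  expect_gt(covered / reps, 0.95 - 3 * sqrt(0.95 * 0.05 / reps))
  expect_lt(covered / reps, 1.0)
})

test_that("sign test reproduces hand-enumerated binomial probabilities", {
  mk <- function(k, n) {
    data.frame(rsid = sprintf("rs%d", 1:n),
               case_eaf = ifelse(seq_len(n) <= k, 0.6, 0.4),
               control_eaf = 0.5,
               or = ifelse(seq_len(n) <= k, 1.2, 0.8))
  }
  r <- sign_test(mk(8, 8))
  expect_equal(r$k, 8L)
  expect_equal(r$p, 2 * 0.5^8)       # 0.0078125, printed 7.8e-3
  expect_equal(sign_test(mk(4, 8))$p, 1.0)
  expect_equal(sign_test(mk(7, 8))$p, 2 * 9 / 256)
  # agrees with the standard exact binomial test under the symmetric null
  for (k in 0:8) {
    expect_equal(sign_test(mk(k, 8))$p,
                 binom.test(k, 8, 0.5)$p.value, tolerance = 1e-12,
                 label = paste("k =", k))
  }
  # OR mode counts adjusted odds ratios instead of frequencies
  expect_equal(sign_test(mk(6, 8), mode = "or")$k, 6L)
  # exact ties are dropped with a warning
  tied <- mk(3, 4); tied$case_eaf[4] <- 0.5
  expect_warning(r <- sign_test(tied), "rs4")
  expect_equal(r$n_snps, 3L)
})

test_that("sign test is conservative under the null", {
  set.seed(91)
  reps <- 400L
  sig <- 0L
  for (r in seq_len(reps)) {
    k <- rbinom(1, 8, 0.5)
    p <- min(1, 2 * min(pbinom(k, 8, 0.5),
                        pbinom(k - 1, 8, 0.5, lower.tail = FALSE)))
    if (p <= 0.05) sig <- sig + 1L
  }
  expect_lte(sig / reps, 0.05 + 3 * sqrt(0.05 * 0.95 / reps))
})

test_that("Cox-Snell R2 matches a brute-force likelihood maximization", {
  y <- c(1, 1, 1, 0, 0, 1, 0, 0, 1, 0, 1, 0)
  x <- c(2, 2, 1, 1, 0, 2, 0, 1, 1, 0, 2, 1)
  fit <- fit_logistic(y, data.frame(x = x))
  # independent route: maximize the Bernoulli likelihood by optim and
  # the null likelihood in closed form
  nll <- function(b) -sum(stats::dbinom(y, 1, plogis(b[1] + b[2] * x),
                                        log = TRUE))
  l1 <- -optim(c(0, 0), nll, method = "BFGS",
               control = list(reltol = 1e-14, maxit = 1000))$value
  pbar <- mean(y)
  l0 <- sum(y) * log(pbar) + sum(1 - y) * log(1 - pbar)
  r2_oracle <- 1 - exp(-2 * (l1 - l0) / length(y))
  expect_equal(cox_snell_r2(fit), r2_oracle, tolerance = 1e-6)
  # an exposure carrying no information leaves R2 at zero
  set.seed(7)
  y2 <- rep(c(0, 1), 50)
  x2 <- rep(c(3, 3, 9, 9), 25)   # orthogonal to y2 by construction
  fit0 <- fit_logistic(y2, data.frame(x = x2))
  expect_equal(cox_snell_r2(fit0), 0, tolerance = 1e-8)
})

test_that("variance-explained correlation behaves at the extremes", {
  co <- small_cohort(seed = 101, n_cases = 200, n_controls = 800,
                     effect_mode = "per_snp_or",
                     per_snp_or = ltl_weights()$glioma_or)
  ltl <- co$samples$ltl_bp
  ve <- variance_explained_correlation(co$genotypes, co$samples, ltl)
  expect_equal(nrow(ve$per_snp), 8L)
  expect_true(all(ve$per_snp$r2_glioma >= 0 & ve$per_snp$r2_glioma <= 1))
  expect_true(all(ve$per_snp$r2_ltl >= 0 & ve$per_snp$r2_ltl <= 1))
  expect_true(ve$r >= -1 && ve$r <= 1)
  # identical vectors correlate perfectly
  expect_equal(cor(ve$per_snp$r2_ltl, ve$per_snp$r2_ltl), 1.0)
})

test_that("septile odds ratios use the fourth septile as reference", {
  co <- simulate_cohort(sim_config(800, 2800, ltl_weights(),
                                   effect_mode = "score_or_per_sd",
                                   or_per_sd = 1.4, seed = 111))
  scores <- score_cohort(co$genotypes, co$weights, co$samples)
  sep <- septile_association(scores, co$samples)
  expect_equal(sep$per_septile$or[4], 1.0)
  expect_equal(sep$trend$term, "septile_idx")
  expect_gt(sep$trend$or, 1)
  expect_gt(sep$extreme$or, 1)
  # extreme contrast consistent with the indicator fit
  expect_equal(sep$extreme$or,
               sep$per_septile$or[7] / sep$per_septile$or[1],
               tolerance = 1e-9)
})

test_that("expected per-septile odds ratios rise monotonically under a positive effect", {
  # average over replicates to approximate large-n expected ORs
  ors <- matrix(NA_real_, 3, 7)
  for (r in 1:3) {
    co <- simulate_cohort(sim_config(1500, 4500, ltl_weights(),
                                     effect_mode = "score_or_per_sd",
                                     or_per_sd = 1.5, seed = 120 + r))
    scores <- score_cohort(co$genotypes, co$weights, co$samples)
    ors[r, ] <- septile_association(scores, co$samples)$per_septile$or
  }
  m <- colMeans(ors)
  expect_gt(cor(m, 1:7), 0.95)
  expect_true(all(diff(m) > -0.1))
  expect_gt(m[7], m[4])
  expect_gt(m[4], m[1])
})

test_that("trend OR matches the brute-force septile-step oracle", {
  co <- simulate_cohort(sim_config(2000, 8000, ltl_weights(),
                                   effect_mode = "score_or_per_sd",
                                   or_per_sd = 1.25, seed = 131))
  scores <- score_cohort(co$genotypes, co$weights, co$samples)
  sep <- septile_association(scores, co$samples)
  # oracle: mean SD-unit step between adjacent septile means among controls
  ctrl <- co$samples$status[match(scores$sample_id,
                                  co$samples$sample_id)] == 0
  sep_means <- tapply(scores$score_sd_units[ctrl],
                      scores$septile[ctrl], mean)
  delta <- mean(diff(sep_means))
  expect_equal(sep$trend$or, exp(log(1.25) * delta), tolerance = 0.05)
})

test_that("single-locus tests recover planted per-allele effects", {
  w <- ltl_weights()
  co <- simulate_cohort(sim_config(1130, 6294, w,
                                   effect_mode = "per_snp_or",
                                   per_snp_or = w$glioma_or, seed = 141))
  sl <- single_locus_tests(co$genotypes, co$samples, w)
  expect_equal(sl$summary$rsid, w$rsid)
  expect_equal(sl$summary$gene, w$gene)
  tert <- sl$summary[sl$summary$rsid == "rs2736100", ]
  expect_gt(tert$ci_hi, 1.39 - 1e-9)
  expect_lt(tert$ci_lo, 1.39 + 1e-9)
  expect_equal(tert$or, 1.39, tolerance = 0.1)
  # and a null SNP stays near 1
  co0 <- simulate_cohort(sim_config(1000, 4000, w,
                                    effect_mode = "null", seed = 142))
  sl0 <- single_locus_tests(co0$genotypes, co0$samples, w)
  expect_true(all(abs(log(sl0$summary$or)) < log(1.25)))
})
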