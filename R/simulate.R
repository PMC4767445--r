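#' Configuration for a synthetic case-control cohort
#'
#' The generator emulates the genotype structure the analysis assumes:
#' unlinked autosomal biallelic SNPs in Hardy-Weinberg equilibrium at
#' the instrument's control effect-allele frequencies, disease status
#' from an additive logistic model, imputation-posterior uncertainty
#' (soft GP triples), missingness, and nuisance covariates (two
#' ancestry PCs, genotyping platform by cohort).
#'
#' Disease models (`effect_mode`):
#' \describe{
#'   \item{`"null"`}{status independent of genotype.}
#'   \item{`"per_snp_or"`}{logit = alpha + sum(log(OR_i) * g_i), one
#'     per-allele odds ratio per SNP.}
#'   \item{`"score_or_per_sd"`}{logit = alpha + log(or_per_sd)/sd_S * S,
#'     where S is the bp score and sd_S its analytic control-population
#'     SD under HWE.}
#' }
#' The intercept alpha is calibrated by bisection so the source
#' population has the requested `baseline_prevalence`; sampling then
#' proceeds by rejection until the case and control quotas are filled.
#' Under case-control sampling the additive logistic odds ratios are
#' preserved regardless of alpha.
#'
#' @param n_cases,n_controls Target sample counts (> 0).
#' @param weights A `weights_table` supplying rsIDs, allele
#'   frequencies (`control_eaf` if present, else `eaf`) and bp weights.
#' @param effect_mode `"null"`, `"per_snp_or"` or `"score_or_per_sd"`.
#' @param per_snp_or Per-allele odds ratios, one per SNP (recycled if
#'   scalar); required for `effect_mode = "per_snp_or"`.
#' @param or_per_sd Odds ratio per control-SD of score; required for
#'   `effect_mode = "score_or_per_sd"`.
#' @param baseline_prevalence Case fraction in the source population.
#' @param gp_frac Fraction of genotypes emitted as soft GP triples.
#' @param gp_noise Upper bound of the per-genotype perturbation epsilon
#'   (drawn uniform on \[0, gp_noise\]); the true class keeps 1 - epsilon.
#' @param missing_rate Per-genotype missingness probability.
#' @param pc1_beta Log-odds effect of PC1 on status (0 = no
#'   confounding; nonzero exercises covariate adjustment).
#' @param ltl_noise_sd SD (bp) of environmental noise added to the
#'   genetic score to form a continuous LTL phenotype.
#' @param cohorts Named character vector mapping cohort label to
#'   platform label.
#' @param cohort_frac Sampling fractions per cohort (default uniform).
#' @param seed RNG seed; all stochastic draws flow from it.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_cases, n_controls, weights,
                       effect_mode = c("null", "per_snp_or",
                                       "score_or_per_sd"),
                       per_snp_or = NULL, or_per_sd = NULL,
                       baseline_prevalence = 0.15,
                       gp_frac = 0, gp_noise = 0, missing_rate = 0,
                       pc1_beta = 0, ltl_noise_sd = 650,
                       cohorts = c(discovery = "illumina"),
                       cohort_frac = NULL, seed = 1L) {
  effect_mode <- match.arg(effect_mode)
  stopifnot(inherits(weights, "weights_table"), nrow(weights) > 0L)
  if (!(n_cases > 0 && n_controls > 0)) {
    stop("n_cases and n_controls must be positive", call. = FALSE)
  }
  if (!(baseline_prevalence > 0 && baseline_prevalence < 1)) {
    stop("baseline_prevalence must be in (0, 1)", call. = FALSE)
  }
  for (r in c(gp_frac = gp_frac, gp_noise = gp_noise,
              missing_rate = missing_rate)) {
    if (!(r >= 0 && r <= 1)) stop("rates must be in [0, 1]", call. = FALSE)
  }
  if (effect_mode == "per_snp_or") {
    if (is.null(per_snp_or)) stop("per_snp_or required", call. = FALSE)
    per_snp_or <- rep_len(per_snp_or, nrow(weights))
    if (any(per_snp_or <= 0)) stop("odds ratios must be > 0", call. = FALSE)
  }
  if (effect_mode == "score_or_per_sd") {
    if (is.null(or_per_sd) || or_per_sd <= 0) {
      stop("or_per_sd must be a positive odds ratio", call. = FALSE)
    }
  }
  if (is.null(cohort_frac)) {
    cohort_frac <- rep(1 / length(cohorts), length(cohorts))
  }
  stopifnot(length(cohort_frac) == length(cohorts),
            abs(sum(cohort_frac) - 1) < 1e-8)
  structure(list(n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 weights = weights, effect_mode = effect_mode,
                 per_snp_or = per_snp_or, or_per_sd = or_per_sd,
                 baseline_prevalence = baseline_prevalence,
                 gp_frac = gp_frac, gp_noise = gp_noise,
                 missing_rate = missing_rate, pc1_beta = pc1_beta,
                 ltl_noise_sd = ltl_noise_sd, cohorts = cohorts,
                 cohort_frac = cohort_frac, seed = as.integer(seed)),
            class = "sim_config")
}

# Per-individual genetic contribution to the logit, given integer
# genotypes (n x K).
sim_logit_effect <- function(g, config) {
  switch(config$effect_mode,
    null = rep(0, nrow(g)),
    per_snp_or = as.vector(g %*% log(config$per_snp_or)),
    score_or_per_sd = {
      s <- as.vector(g %*% config$weights$bp_weight)
      s * log(config$or_per_sd) / score_moments(config$weights)$sd
    })
}

# Calibrate the logistic intercept to the target population prevalence
# by bisection over a fixed Monte Carlo draw of linear predictors.
calibrate_alpha <- function(config, n_mc = 100000L) {
  p <- sim_eaf(config$weights)
  g <- vapply(p, function(pi) stats::rbinom(n_mc, 2L, pi),
              integer(n_mc))
  eta <- sim_logit_effect(g, config)
  if (config$pc1_beta != 0) {
    eta <- eta + config$pc1_beta * stats::rnorm(n_mc)
  }
  target <- config$baseline_prevalence
  f <- function(a) mean(stats::plogis(a + eta)) - target
  lo <- -50; hi <- 50
  if (f(lo) > 0 || f(hi) < 0) {
    stop("unreachable baseline prevalence (intercept diverges)",
         call. = FALSE)
  }
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
    if (hi - lo < 1e-10) break
  }
  (lo + hi) / 2
}

#' Simulate hard genotypes under Hardy-Weinberg equilibrium
#'
#' Each SNP is drawn independently; the long-allele count of each
#' individual at SNP i is Binomial(2, p_i), where p_i is the
#' instrument's control effect-allele frequency.
#'
#' @param n Number of individuals.
#' @param weights A `weights_table`.
#' @return Integer matrix n x SNPs of long-allele counts (no row
#'   names; naming happens at cohort assembly).
#' @export
simulate_genotypes <- function(n, weights) {
  stopifnot(inherits(weights, "weights_table"))
  p <- sim_eaf(weights)
  g <- vapply(p, function(pi) stats::rbinom(n, 2L, pi), integer(n))
  if (n == 1L) g <- matrix(g, nrow = 1L)
  colnames(g) <- weights$rsid
  g
}

# GP triple for a true genotype class with perturbation epsilon.
# Homozygote truth leaks 2/3 of epsilon to the adjacent heterozygote
# class; heterozygote truth splits epsilon equally between the two
# homozygote classes.
gp_triple <- function(g, eps) {
  switch(as.character(g),
         "0" = c(1 - eps, 2 * eps / 3, eps / 3),
         "1" = c(eps / 2, 1 - eps, eps / 2),
         "2" = c(eps / 3, 2 * eps / 3, 1 - eps))
}

#' Simulate a full case-control cohort
#'
#' Draws genotypes under HWE, assigns case/control status from the
#' configured logistic model, and rejection-samples until the case and
#' control quotas are both met.  PCs are standard normal (PC1 enters
#' the disease model only when `pc1_beta` is nonzero); cohort and
#' platform labels are assigned multinomially; soft GP triples,
#' expected dosages and missingness are applied after sampling.  A
#' continuous LTL phenotype (`ltl_bp` = genetic score + Gaussian noise)
#' is included for variance-explained analyses.  Fully deterministic
#' given `config$seed`.
#'
#' @param config A `sim_config`.
#' @return A `sim_cohort`: list with `genotypes` (a
#'   `genotype_matrix`), `samples` (a `sample_table` with extra column
#'   `ltl_bp`), `gp` (n x SNP x 3 array of GP triples, or NULL),
#'   `weights`, and `truth` (the generating parameter values).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  alpha <- if (config$effect_mode == "null" && config$pc1_beta == 0) {
    stats::qlogis(config$baseline_prevalence)
  } else {
    calibrate_alpha(config)
  }
  K <- nrow(config$weights)
  need_cases <- config$n_cases
  need_controls <- config$n_controls
  acc_g <- list(); acc_pc1 <- list(); acc_pc2 <- list()
  acc_status <- list()
  batch <- max(2000L, ceiling((need_cases + need_controls) / 2))
  guard <- 0L
  while (need_cases > 0L || need_controls > 0L) {
    guard <- guard + 1L
    if (guard > 10000L) {
      stop("rejection sampling failed to fill quotas", call. = FALSE)
    }
    g <- simulate_genotypes(batch, config$weights)
    pc1 <- stats::rnorm(batch); pc2 <- stats::rnorm(batch)
    eta <- alpha + sim_logit_effect(g, config) + config$pc1_beta * pc1
    status <- stats::rbinom(batch, 1L, stats::plogis(eta))
    keep_case <- which(status == 1L)[seq_len(min(need_cases,
                                                 sum(status == 1L)))]
    keep_ctrl <- which(status == 0L)[seq_len(min(need_controls,
                                                 sum(status == 0L)))]
    keep <- sort(c(keep_case, keep_ctrl))
    if (length(keep) > 0L) {
      acc_g[[guard]] <- g[keep, , drop = FALSE]
      acc_pc1[[guard]] <- pc1[keep]; acc_pc2[[guard]] <- pc2[keep]
      acc_status[[guard]] <- status[keep]
      need_cases <- need_cases - length(keep_case)
      need_controls <- need_controls - length(keep_ctrl)
    }
  }
  g <- do.call(rbind, acc_g)
  status <- unlist(acc_status)
  n <- length(status)
  ids <- sprintf("S%06d", seq_len(n))
  rownames(g) <- ids

  cohort_idx <- sample.int(length(config$cohorts), n, replace = TRUE,
                           prob = config$cohort_frac)
  samples <- as_sample_table(data.frame(
    sample_id = ids, status = status,
    pc1 = unlist(acc_pc1), pc2 = unlist(acc_pc2),
    platform = unname(config$cohorts[cohort_idx]),
    cohort = names(config$cohorts)[cohort_idx],
    stringsAsFactors = FALSE))
  samples$ltl_bp <- as.vector(g %*% config$weights$bp_weight) +
    stats::rnorm(n, 0, config$ltl_noise_sd)

  dosage <- matrix(as.numeric(g), n, K, dimnames = list(ids, colnames(g)))
  gpmax <- matrix(1, n, K, dimnames = dimnames(dosage))
  gp_arr <- NULL
  if (config$gp_frac > 0) {
    gp_arr <- array(NA_real_, c(n, K, 3),
                    dimnames = list(ids, colnames(g), NULL))
    soft <- matrix(stats::runif(n * K) < config$gp_frac, n, K)
    eps <- matrix(stats::runif(n * K, 0, config$gp_noise), n, K)
    for (k in seq_len(K)) {
      for (i in which(soft[, k])) {
        trip <- gp_triple(g[i, k], eps[i, k])
        gp_arr[i, k, ] <- trip
        gpmax[i, k] <- max(trip)
        dosage[i, k] <- trip[2] + 2 * trip[3]
      }
    }
  }
  if (config$missing_rate > 0) {
    dosage[matrix(stats::runif(n * K) < config$missing_rate, n, K)] <-
      NA_real_
  }
  truth <- list(effect_mode = config$effect_mode,
                per_snp_or = config$per_snp_or,
                or_per_sd = config$or_per_sd,
                baseline_prevalence = config$baseline_prevalence,
                alpha = alpha, pc1_beta = config$pc1_beta,
                gp_frac = config$gp_frac, gp_noise = config$gp_noise,
                missing_rate = config$missing_rate,
                ltl_noise_sd = config$ltl_noise_sd,
                n_cases = config$n_cases, n_controls = config$n_controls,
                seed = config$seed)
  structure(list(genotypes = genotype_matrix(dosage, gpmax,
                                             source = rep("imputed", K)),
                 samples = samples, gp = gp_arr,
                 weights = config$weights, truth = truth),
            class = "sim_cohort")
}

# REF partner for each effect (ALT) allele, avoiding strand-ambiguous
# A/T and C/G pairs.
ref_partner <- c(A = "G", C = "T", G = "A", T = "C")

#' Write a simulated cohort to disk
#'
#' Emits `genotypes.vcf` (VCF 4.2, FORMAT GT:DS:GP with the effect
#' allele as ALT so DS is the long-allele dosage), `samples.tsv` and
#' `truth.json`.  Byte-identical for the same cohort object.
#'
#' @param cohort A `sim_cohort`.
#' @param out_dir Output directory (created if absent).
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_cohort <- function(cohort, out_dir) {
  stopifnot(inherits(cohort, "sim_cohort"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- cohort$weights
  dosage <- cohort$genotypes$dosage
  n <- nrow(dosage); K <- ncol(dosage)
  ids <- rownames(dosage)

  vcf_path <- file.path(out_dir, "genotypes.vcf")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=ltlmr_simulate",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage of ALT allele\">",
    "##FORMAT=<ID=GP,Number=3,Type=Float,Description=\"Genotype posterior probabilities for 0/1/2 copies of ALT\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", ids), collapse = "\t"))
  rows <- character(K)
  for (k in seq_len(K)) {
    alt <- w$effect_allele[k]
    ref <- ref_partner[[alt]]
    cells <- character(n)
    for (i in seq_len(n)) {
      d <- dosage[i, k]
      if (is.na(d)) { cells[i] <- "./.:.:."; next }
      trip <- if (!is.null(cohort$gp) && !is.na(cohort$gp[i, k, 1])) {
        cohort$gp[i, k, ]
      } else {
        g <- round(d); c(g == 0, g == 1, g == 2) * 1
      }
      best <- which.max(trip) - 1L
      gt <- c("0/0", "0/1", "1/1")[best + 1L]
      cells[i] <- sprintf("%s:%.4f:%.4f,%.4f,%.4f",
                          gt, d, trip[1], trip[2], trip[3])
    }
    rows[k] <- paste(c(w$chrom[k], format(1000000L * k),
                       w$rsid[k], ref, alt, ".", "PASS", ".",
                       "GT:DS:GP", cells), collapse = "\t")
  }
  writeLines(c(header, rows), vcf_path)

  samples_path <- file.path(out_dir, "samples.tsv")
  utils::write.table(cohort$samples, samples_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)

  truth_path <- file.path(out_dir, "truth.json")
  jsonlite::write_json(cohort$truth, truth_path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(c(vcf = vcf_path, samples = samples_path, truth = truth_path))
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("sim_cohort: %d cases / %d controls, %d SNPs, effect_mode=%s\n",
              sum(x$samples$status == 1), sum(x$samples$status == 0),
              ncol(x$genotypes$dosage), x$truth$effect_mode))
  invisible(x)
}
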