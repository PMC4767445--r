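#' Covariate-adjusted logistic regression with Wald inference
#'
#' Maximum-likelihood logistic fit (iteratively reweighted least
#' squares via [stats::glm()], convergence tolerance 1e-8, at most 50
#' iterations).  Reports per-term odds ratios exp(beta), Wald 95%
#' confidence intervals exp(beta +/- 1.96 se) and Wald p-values.
#' Non-convergence or quasi-separation (exploding standard errors)
#' flags the fit and suppresses the odds ratios.
#'
#' @param response 0/1 vector (1 = case).
#' @param design Data frame of predictor columns; factors are
#'   expanded to indicators.  Must be full rank.
#' @return A `logistic_fit`: list with `terms` (data frame: term,
#'   estimate, se, or, ci_lo, ci_hi, p), `loglik`, `null_loglik`, `n`,
#'   `converged`.
#' @export
fit_logistic <- function(response, design) {
  stopifnot(is.data.frame(design), length(response) == nrow(design))
  if (length(unique(response)) < 2L) {
    stop("need at least one case and one control", call. = FALSE)
  }
  df <- cbind(data.frame(.y = response), design)
  mm <- stats::model.matrix(.y ~ ., data = df)
  qr_mm <- qr(mm)
  if (qr_mm$rank < ncol(mm)) {
    bad <- colnames(mm)[qr_mm$pivot[(qr_mm$rank + 1):ncol(mm)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  fit <- stats::glm(.y ~ ., data = df, family = stats::binomial(),
                    control = stats::glm.control(epsilon = 1e-8,
                                                 maxit = 50))
  est <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  converged <- isTRUE(fit$converged) && all(is.finite(se)) &&
    max(se) < 1e3
  z <- est / se
  terms <- data.frame(term = names(est), estimate = unname(est),
                      se = unname(se),
                      or = exp(unname(est)),
                      ci_lo = exp(unname(est - 1.96 * se)),
                      ci_hi = exp(unname(est + 1.96 * se)),
                      p = 2 * stats::pnorm(-abs(unname(z))),
                      stringsAsFactors = FALSE)
  if (!converged) terms[, c("or", "ci_lo", "ci_hi")] <- NA_real_
  structure(list(terms = terms,
                 loglik = as.numeric(stats::logLik(fit)),
                 null_loglik = as.numeric(stats::logLik(fit)) -
                   (fit$null.deviance - fit$deviance) / 2,
                 deviance = fit$deviance,
                 null_deviance = fit$null.deviance,
                 n = nrow(df), converged = converged,
                 vcov = stats::vcov(fit)),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("logistic fit (n = %d, logLik = %.2f%s)\n", x$n, x$loglik,
              if (x$converged) "" else ", NOT CONVERGED"))
  print(x$terms, row.names = FALSE, digits = 4)
  invisible(x)
}

# Build the nuisance-covariate data frame; platform is a factor
# (one-hot in the model matrix) and is dropped automatically when the
# cohort was genotyped on a single platform.
covariate_frame <- function(samples, covariates = c("pc1", "pc2",
                                                    "platform")) {
  out <- samples[, intersect(covariates, names(samples)), drop = FALSE]
  if ("platform" %in% names(out)) {
    if (length(unique(out$platform)) < 2L) {
      out$platform <- NULL
    } else {
      out$platform <- factor(out$platform)
    }
  }
  as.data.frame(out)
}

# Extract one exposure row from a logistic_fit.
exposure_row <- function(fit, term) {
  r <- fit$terms[fit$terms$term == term, , drop = FALSE]
  stopifnot(nrow(r) == 1L)
  r
}

#' Score-level case-control association
#'
#' Reports case and control mean scores, their difference in bp and as
#' a percent of the control mean, and covariate-adjusted logistic fits
#' of status on the score per bp and per control-SD.
#'
#' @param scores A `score_table` with `score_bp` and `score_sd_units`.
#' @param samples A `sample_table`.
#' @param covariates Covariate columns (default PCs + platform).
#' @return An `assoc_score` list: `control_mean`, `case_mean`,
#'   `diff_bp`, `pct_diff`, `fit_per_bp`, `fit_per_sd`, and the
#'   exposure rows `per_bp`, `per_sd`.
#' @export
score_association <- function(scores, samples,
                              covariates = c("pc1", "pc2", "platform")) {
  idx <- match(scores$sample_id, samples$sample_id)
  st <- samples$status[idx]
  ok <- !is.na(scores$score_bp)
  control_mean <- mean(scores$score_bp[ok & st == 0])
  case_mean <- mean(scores$score_bp[ok & st == 1])
  cov <- covariate_frame(samples[idx, , drop = FALSE], covariates)
  fit_bp <- fit_logistic(st[ok],
                         cbind(data.frame(score_bp = scores$score_bp[ok]),
                               cov[ok, , drop = FALSE]))
  fit_sd <- fit_logistic(st[ok],
                         cbind(data.frame(score_sd = scores$score_sd_units[ok]),
                               cov[ok, , drop = FALSE]))
  structure(list(control_mean = control_mean, case_mean = case_mean,
                 diff_bp = case_mean - control_mean,
                 pct_diff = 100 * (case_mean - control_mean) / control_mean,
                 fit_per_bp = fit_bp, fit_per_sd = fit_sd,
                 per_bp = exposure_row(fit_bp, "score_bp"),
                 per_sd = exposure_row(fit_sd, "score_sd")),
            class = "assoc_score")
}

#' @export
print.assoc_score <- function(x, ...) {
  cat(sprintf("mean score: cases %.1f bp, controls %.1f bp (diff %.1f bp, %.2f%%)\n",
              x$case_mean, x$control_mean, x$diff_bp, x$pct_diff))
  cat(sprintf("OR per SD = %.3f (95%% CI %.3f-%.3f, p = %.3g)\n",
              x$per_sd$or, x$per_sd$ci_lo, x$per_sd$ci_hi, x$per_sd$p))
  invisible(x)
}

#' Septile-stratified odds ratios and trend test
#'
#' Per-septile odds ratios are from an indicator-coded logistic fit
#' with the median (fourth) septile as reference; the trend OR is from
#' a separate fit with septile entered as an integer 1..7.  The
#' extreme contrast (top vs bottom septile) is derived from the
#' indicator fit.  A septile empty in cases or controls has its OR
#' flagged (NA); the trend is still fit.
#'
#' @param scores A `score_table` with a `septile` column.
#' @param samples A `sample_table`.
#' @param covariates Covariate columns.
#' @param reference Reference septile (default 4).
#' @return An `assoc_septile` list: `per_septile` (data frame septile,
#'   or, ci_lo, ci_hi, p; reference row has OR 1), `trend` (exposure
#'   row of the integer-coded fit), `extreme` (top vs bottom OR, CI,
#'   p), and the underlying fits.
#' @export
septile_association <- function(scores, samples,
                                covariates = c("pc1", "pc2", "platform"),
                                reference = 4L) {
  stopifnot("septile" %in% names(scores))
  idx <- match(scores$sample_id, samples$sample_id)
  st <- samples$status[idx]
  ok <- !is.na(scores$septile)
  sep <- scores$septile[ok]; y <- st[ok]
  cov <- covariate_frame(samples[idx, , drop = FALSE],
                         covariates)[ok, , drop = FALSE]
  levs <- sort(unique(sep))
  f <- stats::relevel(factor(sep, levels = levs),
                      ref = as.character(reference))
  fit_ind <- fit_logistic(y, cbind(data.frame(septile = f), cov))
  tab <- table(factor(sep, levels = 1:7), y)
  populated <- rowSums(tab > 0) == 2L

  per <- data.frame(septile = 1:7, or = NA_real_, ci_lo = NA_real_,
                    ci_hi = NA_real_, p = NA_real_)
  per[per$septile == reference, c("or", "ci_lo", "ci_hi")] <- 1
  for (k in setdiff(1:7, reference)) {
    term <- paste0("septile", k)
    r <- fit_ind$terms[fit_ind$terms$term == term, , drop = FALSE]
    if (nrow(r) == 1L && populated[k]) {
      per[per$septile == k, c("or", "ci_lo", "ci_hi", "p")] <-
        r[, c("or", "ci_lo", "ci_hi", "p")]
    }
  }
  fit_trend <- fit_logistic(y, cbind(data.frame(septile_idx = sep), cov))
  trend <- exposure_row(fit_trend, "septile_idx")

  extreme <- NULL
  t7 <- "septile7"; t1 <- "septile1"
  cn <- colnames(fit_ind$vcov)
  if (all(c(t7, t1) %in% cn)) {
    b <- fit_ind$terms$estimate[match(c(t7, t1), fit_ind$terms$term)]
    v <- fit_ind$vcov[t7, t7] + fit_ind$vcov[t1, t1] -
      2 * fit_ind$vcov[t7, t1]
    d <- b[1] - b[2]; se <- sqrt(v)
    extreme <- data.frame(or = exp(d), ci_lo = exp(d - 1.96 * se),
                          ci_hi = exp(d + 1.96 * se),
                          p = 2 * stats::pnorm(-abs(d / se)))
  }
  structure(list(per_septile = per, trend = trend, extreme = extreme,
                 fit_indicator = fit_ind, fit_trend = fit_trend),
            class = "assoc_septile")
}

#' @export
print.assoc_septile <- function(x, ...) {
  print(x$per_septile, row.names = FALSE, digits = 3)
  cat(sprintf("trend OR per septile = %.3f (95%% CI %.3f-%.3f, p = %.3g)\n",
              x$trend$or, x$trend$ci_lo, x$trend$ci_hi, x$trend$p))
  invisible(x)
}

#' Single-locus allelic association tests
#'
#' One covariate-adjusted logistic fit per instrument SNP, with the
#' long-allele dosage as the exposure (allelic additive model).  An
#' odds ratio above 1 means the long allele is more common in cases.
#'
#' @param genotypes A `genotype_matrix`.
#' @param samples A `sample_table`.
#' @param weights A `weights_table` (gene labels for reporting).
#' @param covariates Covariate columns.
#' @return An `assoc_single_locus` list: `summary` (data frame: rsid,
#'   gene, case_eaf, control_eaf, or, ci_lo, ci_hi, p, converged) and
#'   `fits` (named list of `logistic_fit`).
#' @export
single_locus_tests <- function(genotypes, samples, weights,
                               covariates = c("pc1", "pc2", "platform")) {
  d <- genotypes$dosage
  idx <- match(rownames(d), samples$sample_id)
  st <- samples$status[idx]
  cov <- covariate_frame(samples[idx, , drop = FALSE], covariates)
  fits <- list()
  rows <- vector("list", ncol(d))
  for (k in seq_len(ncol(d))) {
    snp <- colnames(d)[k]
    ok <- !is.na(d[, k])
    fit <- fit_logistic(st[ok],
                        cbind(data.frame(dosage = d[ok, k]),
                              cov[ok, , drop = FALSE]))
    fits[[snp]] <- fit
    r <- exposure_row(fit, "dosage")
    g <- match(snp, weights$rsid)
    rows[[k]] <- data.frame(
      rsid = snp,
      gene = if (is.na(g)) NA_character_ else weights$gene[g],
      case_eaf = mean(d[ok & st == 1, k]) / 2,
      control_eaf = mean(d[ok & st == 0, k]) / 2,
      or = r$or, ci_lo = r$ci_lo, ci_hi = r$ci_hi, p = r$p,
      converged = fit$converged, stringsAsFactors = FALSE)
  }
  structure(list(summary = do.call(rbind, rows), fits = fits),
            class = "assoc_single_locus")
}

#' @export
print.assoc_single_locus <- function(x, ...) {
  print(x$summary, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Binomial sign test of effect-direction concordance
#'
#' Under the null of no LTL-glioma association, the long allele of
#' each unlinked SNP is equally likely to be more or less common in
#' cases than controls.  The test counts SNPs whose long allele is
#' more common in cases (`mode = "frequency"`, the default, compares
#' raw case vs control allele frequencies; `mode = "or"` counts
#' adjusted odds ratios above 1) and computes the two-sided binomial
#' p-value p = min(1, 2 min(P\[X <= k\], P\[X >= k\])) with
#' X ~ Binomial(n, 1/2).  Exact ties are dropped from n with a
#' warning.
#'
#' @param single_locus An `assoc_single_locus` (or its `summary` data
#'   frame).
#' @param mode `"frequency"` or `"or"`.
#' @return A `sign_test_result`: list with `n_snps`, `k` (long allele
#'   more common in cases), `p`, `mode`.
#' @export
sign_test <- function(single_locus, mode = c("frequency", "or")) {
  mode <- match.arg(mode)
  s <- if (inherits(single_locus, "assoc_single_locus")) {
    single_locus$summary
  } else single_locus
  stat <- if (mode == "frequency") {
    s$case_eaf - s$control_eaf
  } else {
    log(s$or)
  }
  ties <- which(stat == 0 | is.na(stat))
  if (length(ties) > 0L) {
    warning("dropping SNP(s) with exactly null effect direction: ",
            paste(s$rsid[ties], collapse = ", "), call. = FALSE)
    stat <- stat[-ties]
  }
  n <- length(stat)
  if (n < 1L) stop("no informative SNPs for the sign test", call. = FALSE)
  k <- sum(stat > 0)
  p <- min(1, 2 * min(stats::pbinom(k, n, 0.5),
                      stats::pbinom(k - 1, n, 0.5, lower.tail = FALSE)))
  structure(list(n_snps = n, k = k, p = p, mode = mode),
            class = "sign_test_result")
}

#' @export
print.sign_test_result <- function(x, ...) {
  cat(sprintf("sign test (%s mode): long allele more common in cases at %d of %d SNPs, two-sided binomial p = %.4g\n",
              x$mode, x$k, x$n_snps, x$p))
  invisible(x)
}

#' Cox-Snell pseudo R-squared of a logistic fit
#'
#' R2 = 1 - (L0/L1)^(2/n), with L0 the intercept-only likelihood.
#'
#' @param fit A `logistic_fit`.
#' @return Value in \[0, 1).
#' @export
cox_snell_r2 <- function(fit) {
  stopifnot(inherits(fit, "logistic_fit"))
  1 - exp(-(fit$null_deviance - fit$deviance) / fit$n)
}

#' Correlation of per-SNP variance explained in LTL vs disease risk
#'
#' For each SNP, computes the Cox-Snell pseudo-R2 from an unadjusted
#' single-SNP logistic fit of case status on dosage, and the Pearson
#' R2 from a linear fit of a continuous LTL phenotype on dosage; then
#' the Pearson correlation of the two R2 vectors across SNPs with a
#' two-sided t-test.
#'
#' @param genotypes A `genotype_matrix`.
#' @param samples A `sample_table`.
#' @param ltl_phenotype Numeric LTL phenotype per sample, aligned to
#'   genotype rows (e.g. the simulator's `ltl_bp` column).
#' @return A `variance_explained` list: `per_snp` (data frame rsid,
#'   r2_glioma, r2_ltl), `r`, `p`.
#' @export
variance_explained_correlation <- function(genotypes, samples,
                                           ltl_phenotype) {
  d <- genotypes$dosage
  stopifnot(length(ltl_phenotype) == nrow(d))
  idx <- match(rownames(d), samples$sample_id)
  st <- samples$status[idx]
  rows <- vector("list", ncol(d))
  for (k in seq_len(ncol(d))) {
    ok <- !is.na(d[, k])
    fit <- fit_logistic(st[ok], data.frame(dosage = d[ok, k]))
    okl <- ok & !is.na(ltl_phenotype)
    r2l <- summary(stats::lm(ltl_phenotype[okl] ~ d[okl, k]))$r.squared
    rows[[k]] <- data.frame(rsid = colnames(d)[k],
                            r2_glioma = cox_snell_r2(fit),
                            r2_ltl = r2l, stringsAsFactors = FALSE)
  }
  per_snp <- do.call(rbind, rows)
  if (nrow(per_snp) < 3L) stop("need at least 3 SNPs", call. = FALSE)
  if (stats::sd(per_snp$r2_glioma) == 0 || stats::sd(per_snp$r2_ltl) == 0) {
    stop("zero-variance R2 vector; correlation undefined", call. = FALSE)
  }
  ct <- stats::cor.test(per_snp$r2_glioma, per_snp$r2_ltl,
                        method = "pearson")
  structure(list(per_snp = per_snp, r = unname(ct$estimate),
                 p = ct$p.value),
            class = "variance_explained")
}

#' @export
print.variance_explained <- function(x, ...) {
  print(x$per_snp, row.names = FALSE, digits = 3)
  cat(sprintf("Pearson r = %.3f, p = %.3g\n", x$r, x$p))
  invisible(x)
}
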