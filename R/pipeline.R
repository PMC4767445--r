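#' Pipeline configuration
#'
#' Collects paths, QC thresholds and analysis switches for
#' [run_pipeline()].  Thresholds default to the study's filter
#' semantics: imputation posterior >= 0.80, SNP call rate >= 98%,
#' control-only HWE p >= 0.001, seven control-defined score strata.
#'
#' @param weights Path to the weights TSV, or a `weights_table`.
#' @param genotypes Path to a VCF (`.vcf`) or dosage TSV, or a
#'   `genotype_matrix`.
#' @param samples Path to the sample TSV, or a `sample_table`.
#' @param out_dir Output directory.
#' @param gp_threshold,call_rate_min,hwe_min_p QC thresholds in \[0, 1\].
#' @param hwe_method `"chisq"` or `"exact"`.
#' @param exclude_genes Genes dropped for the reduced-score analysis.
#' @param n_quantiles Number of score strata (>= 2; default 7).
#' @param covariates Covariates for the logistic fits.
#' @param assume_forward_strand Passed to VCF harmonization.
#' @param seed RNG seed recorded in the summary (the analysis itself
#'   is deterministic).
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(weights, genotypes, samples, out_dir,
                            gp_threshold = 0.80, call_rate_min = 0.98,
                            hwe_min_p = 0.001, hwe_method = "chisq",
                            exclude_genes = c("TERC", "TERT", "RTEL1"),
                            n_quantiles = 7L,
                            covariates = c("pc1", "pc2", "platform"),
                            assume_forward_strand = FALSE, seed = 1L) {
  for (th in c(gp_threshold = gp_threshold,
               call_rate_min = call_rate_min, hwe_min_p = hwe_min_p)) {
    if (!is.finite(th) || th < 0 || th > 1) {
      stop("QC thresholds must lie in [0, 1]", call. = FALSE)
    }
  }
  if (n_quantiles < 2L) stop("n_quantiles must be >= 2", call. = FALSE)
  structure(list(weights = weights, genotypes = genotypes,
                 samples = samples, out_dir = out_dir,
                 gp_threshold = gp_threshold,
                 call_rate_min = call_rate_min, hwe_min_p = hwe_min_p,
                 hwe_method = hwe_method, exclude_genes = exclude_genes,
                 n_quantiles = as.integer(n_quantiles),
                 covariates = covariates,
                 assume_forward_strand = assume_forward_strand,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

stage_log <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

resolve_inputs <- function(config) {
  w <- config$weights
  if (!inherits(w, "weights_table")) w <- read_weights(w)
  s <- config$samples
  if (!inherits(s, "sample_table")) s <- read_samples(s)
  g <- config$genotypes
  if (!inherits(g, "genotype_matrix")) {
    g <- if (grepl("\\.vcf(\\.gz)?$", g)) {
      read_vcf_genotypes(g, w, config$assume_forward_strand)
    } else {
      read_dosage_tsv(g, w)
    }
  }
  list(weights = w, genotypes = g, samples = s)
}

#' Run the full QC -> score -> association pipeline
#'
#' Executes the stages in order and writes a report bundle to
#' `config$out_dir`: `qc_report.json`, `scores.tsv`,
#' `septile_boundaries.json`, `assoc_report.tsv` (one row per fitted
#' term) and `summary.json` (means, differences, ORs, sign test,
#' reduced-score result).  Every stage logs its input/output row
#' counts; the run is deterministic given the inputs.
#'
#' @param config A `pipeline_config`.
#' @return The report bundle, invisibly: list with `qc`, `scores`,
#'   `score_assoc`, `septile_assoc`, `single_locus`, `sign_test`,
#'   `reduced`, `summary`, and `files`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  inp <- resolve_inputs(config)
  stage_log("input", "%d samples, %d instrument SNPs",
            nrow(inp$samples), nrow(inp$weights))

  qc <- run_qc(inp$genotypes, inp$samples,
               gp_threshold = config$gp_threshold,
               call_rate_min = config$call_rate_min,
               hwe_min_p = config$hwe_min_p,
               hwe_method = config$hwe_method)
  stage_log("qc", "samples %d -> %d, SNPs %d -> %d",
            qc$report$n_samples_in, qc$report$n_samples_out,
            qc$report$n_snps_in, qc$report$n_snps_out)

  kept_w <- inp$weights[inp$weights$rsid %in% colnames(qc$genotypes$dosage), ]
  class(kept_w) <- class(inp$weights)
  scores <- score_cohort(qc$genotypes, kept_w, qc$samples,
                         config$n_quantiles)
  stage_log("score", "%d samples scored, control mean %.1f bp, SD %.1f bp",
            sum(!is.na(scores$score_bp)),
            attr(scores, "control_mean"), attr(scores, "control_sd"))

  sa <- score_association(scores, qc$samples, config$covariates)
  sep <- septile_association(scores, qc$samples, config$covariates)
  sl <- single_locus_tests(qc$genotypes, qc$samples, kept_w,
                           config$covariates)
  st <- sign_test(sl)
  stage_log("associate",
            "per-SD OR %.3f, trend OR %.3f, sign test %d/%d (p = %.3g)",
            sa$per_sd$or, sep$trend$or, st$k, st$n_snps, st$p)

  reduced <- NULL
  excl <- intersect(config$exclude_genes, kept_w$gene)
  if (length(excl) > 0L && length(excl) < length(unique(kept_w$gene))) {
    rs <- reduced_score(qc$genotypes, kept_w, excl)
    rs <- standardize(rs, qc$samples)
    reduced <- score_association(rs, qc$samples, config$covariates)
    stage_log("associate", "reduced score (minus %s): diff %.1f bp (%.2f%%)",
              paste(excl, collapse = "/"), reduced$diff_bp,
              reduced$pct_diff)
  }

  varexp <- NULL
  if ("ltl_bp" %in% names(qc$samples)) {
    varexp <- variance_explained_correlation(
      qc$genotypes, qc$samples,
      qc$samples$ltl_bp[match(rownames(qc$genotypes$dosage),
                              qc$samples$sample_id)])
    stage_log("associate", "variance-explained correlation r = %.3f", varexp$r)
  }

  files <- write_report_bundle(config, qc, scores, sa, sep, sl, st,
                               reduced, varexp)
  invisible(list(qc = qc$report, scores = scores, score_assoc = sa,
                 septile_assoc = sep, single_locus = sl, sign_test = st,
                 reduced = reduced, variance_explained = varexp,
                 summary = attr(files, "summary"), files = files))
}

assoc_rows <- function(analysis, fit) {
  data.frame(analysis = analysis, fit$terms,
             n = fit$n, converged = fit$converged,
             stringsAsFactors = FALSE)
}

write_report_bundle <- function(config, qc, scores, sa, sep, sl, st,
                                reduced, varexp) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(qc = file.path(config$out_dir, "qc_report.json"),
             scores = file.path(config$out_dir, "scores.tsv"),
             boundaries = file.path(config$out_dir,
                                    "septile_boundaries.json"),
             assoc = file.path(config$out_dir, "assoc_report.tsv"),
             summary = file.path(config$out_dir, "summary.json"))
  jsonlite::write_json(unclass(qc$report), paths["qc"],
                       auto_unbox = TRUE, digits = 6, pretty = TRUE)
  utils::write.table(
    scores[, c("sample_id", "score_bp", "score_sd_units", "septile")],
    paths["scores"], sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(boundaries = attr(scores, "boundaries"),
                            control_mean = attr(scores, "control_mean"),
                            control_sd = attr(scores, "control_sd")),
                       paths["boundaries"], digits = 6, pretty = TRUE)
  tab <- rbind(assoc_rows("score_per_bp", sa$fit_per_bp),
               assoc_rows("score_per_sd", sa$fit_per_sd),
               assoc_rows("septile_indicator", sep$fit_indicator),
               assoc_rows("septile_trend", sep$fit_trend))
  for (snp in names(sl$fits)) {
    tab <- rbind(tab, assoc_rows(paste0("snp_", snp), sl$fits[[snp]]))
  }
  utils::write.table(tab, paths["assoc"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  summary <- list(
    n_cases = sum(qc$samples$status == 1),
    n_controls = sum(qc$samples$status == 0),
    control_mean_bp = signif(sa$control_mean, 6),
    case_mean_bp = signif(sa$case_mean, 6),
    diff_bp = signif(sa$diff_bp, 6),
    pct_diff = signif(sa$pct_diff, 6),
    or_per_sd = signif(sa$per_sd$or, 6),
    or_per_sd_ci = signif(c(sa$per_sd$ci_lo, sa$per_sd$ci_hi), 6),
    or_per_sd_p = signif(sa$per_sd$p, 6),
    trend_or = signif(sep$trend$or, 6),
    trend_or_p = signif(sep$trend$p, 6),
    extreme_or = if (!is.null(sep$extreme)) signif(sep$extreme$or, 6),
    single_locus = sl$summary,
    sign_test = list(k = st$k, n = st$n_snps, p = signif(st$p, 6)),
    reduced_pct_diff = if (!is.null(reduced)) signif(reduced$pct_diff, 6),
    variance_explained_r = if (!is.null(varexp)) signif(varexp$r, 6),
    seed = config$seed)
  jsonlite::write_json(summary, paths["summary"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null",
                       dataframe = "rows")
  attr(paths, "summary") <- summary
  paths
}

#' Plot septile odds ratios
#'
#' Forest-style plot of per-septile odds ratios (reference septile 4)
#' with 95% confidence intervals, mirroring the dose-response display.
#' Requires ggplot2.
#'
#' @param septile_assoc An `assoc_septile`.
#' @return A ggplot object.
#' @export
plot_septile_or <- function(septile_assoc) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  df <- septile_assoc$per_septile
  ggplot2::ggplot(df, ggplot2::aes(x = .data$septile, y = .data$or)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_lo,
                                          ymax = .data$ci_hi)) +
    ggplot2::scale_x_continuous(breaks = 1:7) +
    ggplot2::labs(x = "Septile of genotypic LTL (control-defined)",
                  y = "Odds ratio vs septile 4") +
    ggplot2::theme_minimal()
}
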