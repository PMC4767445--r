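#' Construct a genotype matrix of long-allele dosages
#'
#' Container for per-sample dosages of the LTL effect ("long") allele,
#' oriented so that 2 means homozygous long.  Dosages may be fractional
#' (expected dosages from imputation posteriors) and NA where missing.
#' `gp_max` holds, per genotype, the largest of the three imputation
#' posterior probabilities; hard calls carry 1.
#'
#' @param dosage Numeric matrix, samples x SNPs, values in \[0, 2\] or NA;
#'   rownames are sample IDs, colnames rsIDs.
#' @param gp_max Optional numeric matrix of the same shape, values in
#'   \[0, 1\]; defaults to 1 everywhere (hard calls).
#' @param source Optional character vector per SNP, `"typed"` or
#'   `"imputed"`.
#' @return A `genotype_matrix` object.
#' @export
genotype_matrix <- function(dosage, gp_max = NULL, source = NULL) {
  stopifnot(is.matrix(dosage), !is.null(rownames(dosage)),
            !is.null(colnames(dosage)))
  ok <- is.na(dosage) | (dosage >= 0 & dosage <= 2)
  if (!all(ok)) stop("dosage values must lie in [0, 2] or be NA",
                     call. = FALSE)
  if (is.null(gp_max)) {
    gp_max <- matrix(1, nrow(dosage), ncol(dosage),
                     dimnames = dimnames(dosage))
  }
  stopifnot(identical(dim(gp_max), dim(dosage)))
  if (!all(is.na(gp_max) | (gp_max >= 0 & gp_max <= 1))) {
    stop("gp_max values must lie in [0, 1]", call. = FALSE)
  }
  if (is.null(source)) source <- rep("typed", ncol(dosage))
  stopifnot(length(source) == ncol(dosage),
            all(source %in% c("typed", "imputed")))
  structure(list(dosage = dosage, gp_max = gp_max,
                 source = stats::setNames(source, colnames(dosage))),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d SNPs (%d imputed), %.2f%% missing\n",
              nrow(x$dosage), ncol(x$dosage),
              sum(x$source == "imputed"),
              100 * mean(is.na(x$dosage))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Expected allele dosage from a genotype-probability triple
#'
#' Standard convention for imputed SNPs: the posterior mean dosage
#' 0*p0 + 1*p1 + 2*p2 over the three genotype classes.
#'
#' @param gp Numeric vector of length 3 (probabilities of 0, 1, 2
#'   copies), or a matrix with 3 columns.
#' @param tol Tolerance for the triple summing to 1.
#' @return Dosage in \[0, 2\]; NA where the triple is not normalizable.
#' @export
expected_dosage <- function(gp, tol = 1e-6) {
  if (is.null(dim(gp))) gp <- matrix(gp, ncol = 3, byrow = TRUE)
  stopifnot(ncol(gp) == 3)
  s <- rowSums(gp)
  bad <- !is.finite(s) | abs(s - 1) > tol | apply(gp < 0, 1, any)
  d <- gp[, 2] + 2 * gp[, 3]
  d[bad] <- NA_real_
  unname(d)
}

#' Orient a variant's dosages to the long-LTL allele
#'
#' Given ALT-allele dosages from a VCF record, returns dosages of the
#' instrument's effect allele: identical when the effect allele is ALT,
#' complemented (2 - dosage) when it is REF.  Strand-ambiguous A/T and
#' C/G variants are rejected unless `assume_forward_strand` is set,
#' because a silent strand flip would invert the score contribution.
#'
#' @param ref,alt Single-base REF and ALT alleles of the variant.
#' @param alt_dosage Numeric vector of ALT dosages in \[0, 2\].
#' @param effect_allele The long-LTL allele from the weights table.
#' @param assume_forward_strand Allow ambiguous A/T / C/G variants.
#' @return Numeric vector of long-allele dosages.
#' @export
harmonize_to_long_allele <- function(ref, alt, alt_dosage, effect_allele,
                                     assume_forward_strand = FALSE) {
  stopifnot(nchar(ref) == 1L, nchar(alt) == 1L)
  ambiguous <- paste0(sort(c(ref, alt)), collapse = "") %in% c("AT", "CG")
  if (ambiguous && !assume_forward_strand) {
    stop(sprintf("variant %s/%s is strand-ambiguous; set assume_forward_strand = TRUE only if the file is known to be forward-stranded",
                 ref, alt), call. = FALSE)
  }
  if (effect_allele == alt) {
    alt_dosage
  } else if (effect_allele == ref) {
    2 - alt_dosage
  } else {
    stop(sprintf("effect allele %s matches neither REF (%s) nor ALT (%s): possible strand issue",
                 effect_allele, ref, alt), call. = FALSE)
  }
}

#' Read case-control genotypes from a VCF
#'
#' Reads a VCF 4.2 file with FORMAT fields GT and optionally DS (ALT
#' dosage) and GP (genotype probabilities in 0/1/2-ALT-copy order),
#' matches records to the instrument by rsID with allele confirmation,
#' and orients every dosage to the long-LTL allele.  Dosage priority:
#' DS, then expected dosage from GP, then hard GT count.  `gp_max` is
#' the maximum of the GP triple where present, 1 otherwise.
#'
#' @param path VCF path.
#' @param weights A `weights_table`; only its SNPs are extracted, in
#'   instrument order.
#' @param assume_forward_strand Passed to [harmonize_to_long_allele()].
#' @return A `genotype_matrix`.
#' @export
read_vcf_genotypes <- function(path, weights, assume_forward_strand = FALSE) {
  stopifnot(inherits(weights, "weights_table"))
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  ids <- fix[, "ID"]
  found <- weights$rsid %in% ids
  if (!all(found)) {
    stop("instrument SNP(s) absent from VCF: ",
         paste(weights$rsid[!found], collapse = ", "), call. = FALSE)
  }
  fmt <- strsplit(unname(vcf@gt[, "FORMAT"]), ":", fixed = TRUE)
  has_ds <- vapply(fmt, function(f) "DS" %in% f, logical(1))
  has_gp <- vapply(fmt, function(f) "GP" %in% f, logical(1))
  gt <- vcfR::extract.gt(vcf, element = "GT")
  ds <- if (any(has_ds)) {
    vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE)
  } else NULL
  gp <- if (any(has_gp)) vcfR::extract.gt(vcf, element = "GP") else NULL
  samples <- colnames(gt)

  n <- length(samples)
  dosage <- matrix(NA_real_, n, nrow(weights),
                   dimnames = list(samples, weights$rsid))
  gpmax <- matrix(1, n, nrow(weights),
                  dimnames = list(samples, weights$rsid))
  imputed <- logical(nrow(weights))

  for (k in seq_len(nrow(weights))) {
    i <- match(weights$rsid[k], ids)
    ref <- fix[i, "REF"]; alt <- fix[i, "ALT"]
    if (is.na(alt) || nchar(ref) != 1L || nchar(alt) != 1L ||
        grepl(",", alt, fixed = TRUE)) {
      stop("instrument SNP ", weights$rsid[k],
           " is not a biallelic SNP in the VCF", call. = FALSE)
    }
    gp_i <- NULL
    if (!is.null(gp) && has_gp[i]) {
      trip <- do.call(rbind, lapply(strsplit(gp[i, ], ",", fixed = TRUE),
                                    function(v) {
                                      if (length(v) == 3) as.numeric(v)
                                      else rep(NA_real_, 3)
                                    }))
      gp_i <- trip
      m <- apply(trip, 1, max)
      gpmax[, k] <- ifelse(is.na(m), 1, m)
      imputed[k] <- TRUE
    }
    alt_dose <- if (!is.null(ds) && has_ds[i]) {
      ds[i, ]
    } else if (!is.null(gp_i)) {
      expected_dosage(gp_i)
    } else {
      counts <- vapply(strsplit(gt[i, ], "[/|]"), function(a) {
        if (anyNA(a) || any(a == ".")) NA_real_
        else sum(a == "1")
      }, numeric(1))
      counts
    }
    dosage[, k] <- harmonize_to_long_allele(
      ref, alt, as.numeric(alt_dose), weights$effect_allele[k],
      assume_forward_strand = assume_forward_strand)
  }
  genotype_matrix(dosage, gpmax,
                  source = ifelse(imputed, "imputed", "typed"))
}

#' Read genotypes from a TSV dosage matrix
#'
#' Dialect: rows are samples (first column `sample_id`), remaining
#' columns are rsIDs holding long-allele dosages in \[0, 2\] or NA.
#' Dosages in this dialect are assumed already oriented to the effect
#' allele.
#'
#' @param path TSV path.
#' @param weights A `weights_table`; columns are reordered to
#'   instrument order and must all be present.
#' @return A `genotype_matrix` (all `gp_max` = 1).
#' @export
read_dosage_tsv <- function(path, weights) {
  stopifnot(inherits(weights, "weights_table"))
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  stopifnot("sample_id" %in% names(df))
  missing_snps <- setdiff(weights$rsid, names(df))
  if (length(missing_snps) > 0L) {
    stop("dosage matrix lacks instrument SNP(s): ",
         paste(missing_snps, collapse = ", "), call. = FALSE)
  }
  m <- as.matrix(df[, weights$rsid, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df$sample_id
  genotype_matrix(m)
}

#' Read a sample table
#'
#' TSV with columns `sample_id`, `status` (1 = case, 0 = control),
#' `pc1`, `pc2` (ancestry principal components), `platform` and
#' `cohort`.
#'
#' @param path TSV path.
#' @return A `sample_table` data frame.
#' @export
read_samples <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  as_sample_table(df)
}

#' Validate a data frame as a sample table
#' @param df Data frame with columns `sample_id`, `status`, `pc1`,
#'   `pc2`, `platform`, `cohort`.
#' @return The validated `sample_table`.
#' @export
as_sample_table <- function(df) {
  required <- c("sample_id", "status", "pc1", "pc2", "platform", "cohort")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("sample table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!all(df$status %in% c(0L, 1L))) {
    stop("status must be 0 (control) or 1 (case)", call. = FALSE)
  }
  if (!all(is.finite(df$pc1)) || !all(is.finite(df$pc2))) {
    stop("principal components must be finite", call. = FALSE)
  }
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample_id(s)", call. = FALSE)
  }
  rownames(df) <- NULL
  class(df) <- c("sample_table", "data.frame")
  df
}
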