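#' Read a SNP weights table for the genotypic LTL instrument
#'
#' The instrument is a set of biallelic SNPs, each contributing
#' `bp_weight` base pairs of estimated leukocyte telomere length (LTL)
#' per copy of its effect ("long") allele.  The file is tab-separated
#' with a named header; required columns are `rsid`, `chrom`, `gene`,
#' `effect_allele`, `eaf`, `beta_ratio` and `bp_weight`.  Optional
#' columns (e.g. `control_eaf`, `gwas_p`, `glioma_or`) are retained as
#' metadata.  Allele frequencies are proportions in (0, 1), not
#' percentages.
#'
#' @param path Path to the TSV file.
#' @return A `weights_table`: a data frame, one row per SNP, in file
#'   order, with class `c("weights_table", "data.frame")`.
#' @seealso [ltl_weights()] for the eight-SNP instrument bundled with
#'   the package, [max_score()] for the score ceiling it implies.
#' @export
read_weights <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  as_weights_table(df)
}

#' Validate a data frame as a weights table
#'
#' @param df Data frame with at least the columns `rsid`, `chrom`,
#'   `gene`, `effect_allele`, `eaf`, `beta_ratio`, `bp_weight`.
#' @return The validated `weights_table` (row order preserved).
#' @export
as_weights_table <- function(df) {
  required <- c("rsid", "chrom", "gene", "effect_allele",
                "eaf", "beta_ratio", "bp_weight")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("weights table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) > 0L) {
    dup <- df$rsid[duplicated(df$rsid)]
    if (length(dup) > 0L) {
      stop("duplicate rsID(s) in weights table: ",
           paste(unique(dup), collapse = ", "), call. = FALSE)
    }
    bad_eaf <- which(!is.finite(df$eaf) | df$eaf <= 0 | df$eaf >= 1)
    if (length(bad_eaf) > 0L) {
      stop("eaf outside (0, 1) for: ",
           paste(df$rsid[bad_eaf], collapse = ", "), call. = FALSE)
    }
    if ("control_eaf" %in% names(df)) {
      bad <- which(!is.finite(df$control_eaf) |
                     df$control_eaf <= 0 | df$control_eaf >= 1)
      if (length(bad) > 0L) {
        stop("control_eaf outside (0, 1) for: ",
             paste(df$rsid[bad], collapse = ", "), call. = FALSE)
      }
    }
    bad_bp <- which(!is.finite(df$bp_weight) | df$bp_weight < 0)
    if (length(bad_bp) > 0L) {
      stop("negative or non-finite bp_weight for: ",
           paste(df$rsid[bad_bp], collapse = ", "), call. = FALSE)
    }
    bad_allele <- which(!df$effect_allele %in% c("A", "C", "G", "T"))
    if (length(bad_allele) > 0L) {
      stop("effect_allele not a single base (A/C/G/T) for: ",
           paste(df$rsid[bad_allele], collapse = ", "), call. = FALSE)
    }
  }
  rownames(df) <- NULL
  class(df) <- c("weights_table", "data.frame")
  df
}

#' Write a weights table to TSV
#'
#' Inverse of [read_weights()]: re-reading the written file reproduces
#' every field.
#'
#' @param weights A `weights_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_weights <- function(weights, path) {
  stopifnot(inherits(weights, "weights_table"))
  utils::write.table(weights, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' The eight-SNP LTL instrument bundled with the package
#'
#' Eight unlinked autosomal SNPs associated with leukocyte telomere
#' length in the ENGAGE Consortium meta-analysis, with per-allele
#' effects in base pairs.  `eaf` is the ENGAGE effect-allele frequency;
#' `control_eaf` the frequency among glioma-study controls (used by the
#' simulator and analytic expectations); `glioma_or` the reported
#' per-allele glioma odds ratio (used only to parameterize simulations).
#'
#' @return A `weights_table` with 8 rows.
#' @export
ltl_weights <- function() {
  read_weights(system.file("extdata", "ltl_weights.tsv",
                           package = "ltlmr", mustWork = TRUE))
}

#' Maximum possible score of an instrument
#'
#' The score of an individual homozygous for the long allele at every
#' SNP: twice the sum of the per-allele bp weights.  For the bundled
#' eight-SNP instrument this is 1215.6 bp.
#'
#' @param weights A `weights_table`.
#' @return Maximum score in bp.
#' @export
max_score <- function(weights) {
  stopifnot(inherits(weights, "weights_table"))
  if (nrow(weights) == 0L) return(0)
  2 * sum(weights$bp_weight)
}

# Simulation/analytic allele frequency: control column when present.
sim_eaf <- function(weights) {
  if ("control_eaf" %in% names(weights)) weights$control_eaf else weights$eaf
}

#' Analytic moments of the score under Hardy-Weinberg equilibrium
#'
#' For unlinked SNPs in HWE with effect-allele frequencies p_i and
#' weights w_i, allele dosages are independent Binomial(2, p_i), so the
#' score has mean sum(2 p_i w_i) and variance sum(w_i^2 2 p_i (1-p_i)).
#' Frequencies are taken from `control_eaf` when present, else `eaf`.
#'
#' @param weights A `weights_table`.
#' @return List with `mean` and `sd` of the score, in bp.
#' @export
score_moments <- function(weights) {
  stopifnot(inherits(weights, "weights_table"))
  p <- sim_eaf(weights)
  w <- weights$bp_weight
  list(mean = sum(2 * p * w), sd = sqrt(sum(w^2 * 2 * p * (1 - p))))
}

#' @export
print.weights_table <- function(x, ...) {
  cat(sprintf("LTL instrument: %d SNP(s), max score %.1f bp\n",
              nrow(x), max_score(x)))
  print.data.frame(x, ...)
  invisible(x)
}
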