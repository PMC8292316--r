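#' Construct a genotype set
#'
#' Bundles an allele-dosage matrix with its variant metadata and per-variant
#' GWAS summary-statistic effect sizes. Dosages count copies of the effect
#' allele (0, 1 or 2; `NA` for a missing call).
#'
#' @param dosages Numeric matrix, subjects in rows, variants in columns;
#'   entries in `{0, 1, 2, NA}`. Row names, if present, must equal `subjects`.
#' @param variants Data frame with one row per column of `dosages`, columns
#'   `variant_id`, `chrom`, `pos`, `effect_allele`, `other_allele`,
#'   `effect_size`, `maf`.
#' @param subjects Character vector of subject identifiers, one per row.
#' @param exclusion_flags Optional data frame with columns `subject_id` and
#'   `reason` listing externally supplied exclusions (e.g. reported-sex
#'   mismatch, duplicate sample); these are pass-through flags, not computed
#'   here.
#' @return An object of class `"genotype_set"`.
#' @export
genotype_set <- function(dosages, variants, subjects,
                         exclusion_flags = NULL) {
  dosages <- as.matrix(dosages)
  if (nrow(dosages) != length(subjects))
    stop("genotype_set: one dosage row per subject required")
  if (ncol(dosages) != nrow(variants))
    stop("genotype_set: one variant record per dosage column required")
  need <- c("variant_id", "chrom", "pos", "effect_allele", "other_allele",
            "effect_size", "maf")
  miss <- setdiff(need, names(variants))
  if (length(miss))
    stop("genotype_set: variant table missing columns: ",
         paste(miss, collapse = ", "))
  bad <- dosages[!is.na(dosages)]
  if (length(bad) && !all(bad %in% c(0, 1, 2)))
    stop("genotype_set: dosages must be 0, 1, 2 or NA")
  rownames(dosages) <- subjects
  colnames(dosages) <- variants$variant_id
  if (is.null(exclusion_flags))
    exclusion_flags <- data.frame(subject_id = character(),
                                  reason = character())
  structure(
    list(dosages = dosages, variants = as.data.frame(variants),
         subjects = as.character(subjects),
         exclusion_flags = as.data.frame(exclusion_flags)),
    class = "genotype_set"
  )
}

#' @export
print.genotype_set <- function(x, ...) {
  cat("Genotype set: ", length(x$subjects), " subjects x ",
      nrow(x$variants), " variants\n", sep = "")
  cr <- mean(!is.na(x$dosages))
  cat(sprintf("  overall call rate: %.4f\n", cr))
  if (nrow(x$exclusion_flags))
    cat("  flagged subjects:", nrow(x$exclusion_flags), "\n")
  invisible(x)
}

#' Quality-control and scoring thresholds
#'
#' Defaults follow the conventional pipeline for array genotypes feeding a
#' polygenic score: samples with call rate below 99% are dropped first, then
#' variants are required (on the retained samples) to have call rate at least
#' 98%, minor allele frequency at least 0.005 and an autosomal chromosome;
#' scoring additionally restricts to MAF >= 0.1 outside the MHC region. The
#' MHC window defaults to the conventional GRCh37 chromosome-6 span
#' 25,000,000 to 34,000,000 (half-open).
#'
#' @param sample_call_rate_min Minimum per-sample call rate.
#' @param variant_call_rate_min Minimum per-variant call rate (after sample
#'   removal).
#' @param maf_min_qc Minimum minor allele frequency for a variant to survive QC.
#' @param autosomes_only Drop variants on non-autosomal chromosomes?
#' @param pgs_maf_min Minimum MAF for a variant to enter the score.
#' @param mhc_window List with `chrom`, `start`, `end` (half-open positions)
#'   excluded from scoring.
#' @return An object of class `"qc_thresholds"`.
#' @export
qc_thresholds <- function(sample_call_rate_min = 0.99,
                          variant_call_rate_min = 0.98,
                          maf_min_qc = 0.005,
                          autosomes_only = TRUE,
                          pgs_maf_min = 0.1,
                          mhc_window = list(chrom = "6",
                                            start = 25e6, end = 34e6)) {
  stopifnot(sample_call_rate_min > 0, sample_call_rate_min <= 1,
            variant_call_rate_min > 0, variant_call_rate_min <= 1,
            maf_min_qc > 0, maf_min_qc <= 1,
            pgs_maf_min > 0, pgs_maf_min <= 1,
            mhc_window$start < mhc_window$end)
  structure(list(sample_call_rate_min = sample_call_rate_min,
                 variant_call_rate_min = variant_call_rate_min,
                 maf_min_qc = maf_min_qc,
                 autosomes_only = autosomes_only,
                 pgs_maf_min = pgs_maf_min,
                 mhc_window = mhc_window),
            class = "qc_thresholds")
}

minor_af <- function(freq) pmin(freq, 1 - freq)

# per-variant effect-allele frequency and call rate on a dosage matrix
variant_stats <- function(dosages) {
  called <- colSums(!is.na(dosages))
  af <- colSums(dosages, na.rm = TRUE) / (2 * pmax(called, 1L))
  list(call_rate = called / nrow(dosages),
       af = af, maf = minor_af(af))
}

#' Quality-control filter for a genotype set
#'
#' Applies the fixed QC sequence: (1) remove subjects carrying an external
#' exclusion flag (duplicate, reported-sex mismatch); (2) remove subjects
#' whose call rate falls below `sample_call_rate_min`; (3) on the retained
#' subjects, recompute per-variant call rate and MAF and remove variants
#' failing `variant_call_rate_min`, `maf_min_qc`, or (when `autosomes_only`)
#' a non-autosomal chromosome label. Sample removal precedes the variant
#' recomputation, so variant statistics reflect only retained subjects.
#'
#' @param genotypes A [genotype_set()].
#' @param thresholds A [qc_thresholds()].
#' @return The filtered `genotype_set`, with the variant table's `maf` column
#'   updated to the post-QC values and an attribute `"qc_log"`: a data frame
#'   of per-step removal counts.
#' @export
qc_filter <- function(genotypes, thresholds = qc_thresholds()) {
  stopifnot(inherits(genotypes, "genotype_set"),
            inherits(thresholds, "qc_thresholds"))
  d <- genotypes$dosages
  if (nrow(d) == 0L || ncol(d) == 0L) stop("qc_filter: empty genotype set")
  log <- list()

  flagged <- genotypes$subjects %in% genotypes$exclusion_flags$subject_id
  log$subjects_flagged <- sum(flagged)
  d <- d[!flagged, , drop = FALSE]

  s_cr <- rowMeans(!is.na(d))
  low <- s_cr < thresholds$sample_call_rate_min
  log$subjects_low_call_rate <- sum(low)
  d <- d[!low, , drop = FALSE]
  if (nrow(d) == 0L) stop("qc_filter: all subjects removed")

  vs <- variant_stats(d)
  v_keep <- vs$call_rate >= thresholds$variant_call_rate_min &
    vs$maf >= thresholds$maf_min_qc
  if (thresholds$autosomes_only) {
    auto <- as.character(genotypes$variants$chrom) %in% as.character(1:22)
    v_keep <- v_keep & auto
    log$variants_non_autosomal <- sum(!auto)
  }
  log$variants_removed <- sum(!v_keep)
  d <- d[, v_keep, drop = FALSE]

  variants <- genotypes$variants[v_keep, , drop = FALSE]
  variants$maf <- vs$maf[v_keep]
  out <- genotype_set(
    d, variants, rownames(d),
    genotypes$exclusion_flags[0, , drop = FALSE]
  )
  attr(out, "qc_log") <- data.frame(step = names(log),
                                    removed = unlist(log, use.names = FALSE))
  out
}

#' Compute the weighted additive polygenic score
#'
#' Restricts to variants with post-QC MAF at least `pgs_maf_min` and position
#' outside the MHC window, then computes for every subject
#' \deqn{PGS = \sum_j S_j G_j}
#' where `S_j` is the GWAS summary-statistic effect size of the effect allele
#' and `G_j` in 0, 1, 2 its dosage. A missing dosage contributes the
#' variant's mean dosage, `2 * effect-allele frequency`, so the score is
#' defined for every subject.
#'
#' @param genotypes A quality-controlled [genotype_set()].
#' @param thresholds A [qc_thresholds()] (only the scoring fields are used).
#' @return Named numeric vector of raw scores, one per subject, with an
#'   attribute `"n_variants_used"`.
#' @export
compute_pgs <- function(genotypes, thresholds = qc_thresholds()) {
  stopifnot(inherits(genotypes, "genotype_set"))
  v <- genotypes$variants
  in_mhc <- as.character(v$chrom) == as.character(thresholds$mhc_window$chrom) &
    v$pos >= thresholds$mhc_window$start &
    v$pos < thresholds$mhc_window$end
  keep <- v$maf >= thresholds$pgs_maf_min & !in_mhc
  if (!any(keep)) stop("compute_pgs: no variants pass the scoring filters")

  d <- genotypes$dosages[, keep, drop = FALSE]
  s <- v$effect_size[keep]
  # mean-dosage imputation for missing calls, from the effect-allele frequency
  af <- variant_stats(d)$af
  for (j in which(colSums(is.na(d)) > 0L))
    d[is.na(d[, j]), j] <- 2 * af[j]
  raw <- drop(d %*% s)
  names(raw) <- genotypes$subjects
  attr(raw, "n_variants_used") <- sum(keep)
  raw
}

#' Standardize polygenic scores
#'
#' Mean-centres and scales to unit sample standard deviation (denominator
#' `n - 1`).
#'
#' @param raw Numeric vector of raw scores, length at least 2.
#' @return Numeric vector with sample mean 0 and sample SD 1; names kept.
#' @export
standardize_scores <- function(raw) {
  stopifnot(is.numeric(raw), length(raw) >= 2L, all(is.finite(raw)))
  s <- stats::sd(raw)
  if (s == 0) stop("standardize_scores: scores are constant")
  out <- as.vector((raw - mean(raw)) / s)
  names(out) <- names(raw)
  out
}

#' Assign morning/middle/evening tertile groups
#'
#' Ranks subjects by score (ascending; ties broken stably by subject
#' identifier) and labels the bottom third `morning`, the top third
#' `evening`, and the remainder `middle`. When `n` is not divisible by 3 the
#' middle group absorbs the remainder, so group sizes never differ by more
#' than 2.
#'
#' Higher scores correspond to later sleep midpoints, hence the top tertile
#' is the evening-inclined group.
#'
#' @param scores Named numeric vector of (standardized) scores; names are the
#'   subject identifiers used for tie-breaking.
#' @return Factor of labels `morning`/`middle`/`evening`, named by subject,
#'   in the input order.
#' @export
assign_tertiles <- function(scores) {
  n <- length(scores)
  if (n < 3L) stop("assign_tertiles: need at least 3 subjects")
  ids <- names(scores) %||% as.character(seq_len(n))
  ord <- order(scores, ids)
  n_tail <- n %/% 3L
  lab <- rep("middle", n)
  lab[ord[seq_len(n_tail)]] <- "morning"
  lab[ord[seq.int(n - n_tail + 1L, n)]] <- "evening"
  out <- factor(lab, levels = c("morning", "middle", "evening"))
  names(out) <- ids
  out
}

#' Full polygenic-score pipeline for one genotype set
#'
#' Convenience wrapper: [qc_filter()], [compute_pgs()],
#' [standardize_scores()], [assign_tertiles()].
#'
#' @param genotypes A [genotype_set()].
#' @param thresholds A [qc_thresholds()].
#' @return An object of class `"pgs_result"`: a data frame with columns
#'   `subject_id`, `raw_score`, `z_score`, `group`, plus attributes `"qc_log"`
#'   and `"n_variants_used"`.
#' @export
pgs_pipeline <- function(genotypes, thresholds = qc_thresholds()) {
  qc <- qc_filter(genotypes, thresholds)
  raw <- compute_pgs(qc, thresholds)
  z <- standardize_scores(raw)
  grp <- assign_tertiles(z)
  out <- data.frame(subject_id = names(raw), raw_score = unname(raw),
                    z_score = unname(z), group = unname(grp),
                    stringsAsFactors = FALSE)
  attr(out, "qc_log") <- attr(qc, "qc_log")
  attr(out, "n_variants_used") <- attr(raw, "n_variants_used")
  class(out) <- c("pgs_result", "data.frame")
  out
}

#' @export
print.pgs_result <- function(x, ...) {
  cat("Polygenic score result: ", nrow(x), " subjects, ",
      attr(x, "n_variants_used"), " variants scored\n", sep = "")
  print(table(x$group))
  invisible(x)
}
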