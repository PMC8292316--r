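#' Run configuration for the full analysis
#'
#' Collects every analysis threshold with defaults matching the study
#' conventions: QC call-rate minima 0.99 (samples) and 0.98 (variants), QC
#' MAF 0.005, scoring MAF 0.1 with the MHC window excluded, a 240-minute
#' event retention threshold, and the 2019 spring transition date.
#'
#' @param dst_date Transition Sunday.
#' @param qc A [qc_thresholds()].
#' @param min_event_minutes Retention threshold for [filter_min_duration()].
#' @param var_equal Pooled-variance t-tests instead of Welch?
#' @param seed Seed recorded for provenance (the analysis itself is
#'   deterministic; only the simulator consumes seeds).
#' @return Object of class `"run_config"`.
#' @export
run_config <- function(dst_date = as.Date("2019-03-10"),
                       qc = qc_thresholds(),
                       min_event_minutes = 240,
                       var_equal = FALSE,
                       seed = 1L) {
  dst_date <- as.Date(dst_date)
  if (day_index(dst_date) != 0L)
    stop("run_config: dst_date must be a Sunday")
  structure(list(dst_date = dst_date, qc = qc,
                 min_event_minutes = min_event_minutes,
                 var_equal = var_equal, seed = as.integer(seed)),
            class = "run_config")
}

SLEEP_COLS <- c("subject_id", "start", "end", "minutes_asleep",
                "minutes_in_bed")

#' Read a sleep-event CSV
#'
#' Expects the header `subject_id,start,end,minutes_asleep,minutes_in_bed`
#' with ISO-8601 local wall-clock timestamps (no zone offset). Rows failing
#' validation (unparseable timestamps, end not after start, non-positive or
#' inconsistent minutes) abort in strict mode; in lenient mode they are
#' dropped and reported in the `"rejected"` attribute (row numbers and
#' reasons).
#'
#' @param path CSV path.
#' @param strict Abort on the first invalid row instead of dropping it?
#' @return Data frame of valid events with `POSIXct` timestamps; attribute
#'   `"rejected"` is a data frame of dropped rows' line numbers and reasons.
#' @export
read_sleep_events <- function(path, strict = FALSE) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  miss <- setdiff(SLEEP_COLS, names(raw))
  if (length(miss))
    stop("read_sleep_events: missing columns: ", paste(miss, collapse = ", "))
  start <- parse_ts(raw$start)
  end <- parse_ts(raw$end)
  asleep <- suppressWarnings(as.numeric(raw$minutes_asleep))
  in_bed <- suppressWarnings(as.numeric(raw$minutes_in_bed))

  reason <- rep(NA_character_, nrow(raw))
  reason[is.na(start) | is.na(end)] <- "unparseable timestamp"
  bad_min <- is.na(reason) & (is.na(asleep) | is.na(in_bed) |
                                asleep <= 0 | asleep > in_bed)
  reason[bad_min] <- "invalid minutes"
  reason[is.na(reason) & end <= start] <- "end not after start"

  bad <- which(!is.na(reason))
  if (length(bad) && strict)
    stop("read_sleep_events: row ", bad[1] + 1L, ": ", reason[bad[1]])
  ok <- is.na(reason)
  out <- data.frame(subject_id = raw$subject_id[ok],
                    start = start[ok], end = end[ok],
                    minutes_asleep = asleep[ok], minutes_in_bed = in_bed[ok],
                    stringsAsFactors = FALSE)
  attr(out, "rejected") <- data.frame(line = bad + 1L, reason = reason[bad])
  out
}

#' Write a sleep-event CSV
#'
#' Deterministic output: fixed column order, ISO-8601 timestamps, no
#' quoting, no row names. Identical tables give identical bytes.
#'
#' @param events Event data frame (`POSIXct` or character timestamps).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sleep_events <- function(events, path) {
  out <- events[, SLEEP_COLS]
  if (inherits(out$start, "POSIXct")) out$start <- format_ts(out$start)
  if (inherits(out$end, "POSIXct")) out$end <- format_ts(out$end)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a genotype set as TSV files
#'
#' The dosage matrix goes to `dosage_path` (first column `subject_id`, then
#' one column per variant, `NA` for missing calls); the variant table to
#' `variant_path` (`variant_id`, `chrom`, `pos`, `effect_allele`,
#' `other_allele`, `effect_size`, `maf`).
#'
#' @param genotypes A [genotype_set()].
#' @param dosage_path,variant_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_genotypes <- function(genotypes, dosage_path, variant_path) {
  d <- as.data.frame(genotypes$dosages)
  d <- cbind(subject_id = genotypes$subjects, d)
  utils::write.table(d, dosage_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.table(genotypes$variants, variant_path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(c(dosage_path, variant_path))
}

#' Read a genotype set from TSV files
#'
#' Inverse of [write_genotypes()].
#'
#' @param dosage_path,variant_path Input paths.
#' @param exclusion_flags Optional pass-through exclusion table (columns
#'   `subject_id`, `reason`).
#' @return A [genotype_set()].
#' @export
read_genotypes <- function(dosage_path, variant_path,
                           exclusion_flags = NULL) {
  d <- utils::read.delim(dosage_path, stringsAsFactors = FALSE,
                         check.names = FALSE)
  v <- utils::read.delim(variant_path, stringsAsFactors = FALSE,
                         colClasses = list(chrom = "character"))
  subjects <- as.character(d$subject_id)
  genotype_set(as.matrix(d[, -1, drop = FALSE]), v, subjects,
               exclusion_flags = exclusion_flags)
}

#' Write the per-subject polygenic score table
#'
#' @param pgs A `pgs_result`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_pgs_table <- function(pgs, path) {
  utils::write.table(as.data.frame(pgs), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a full analysis report bundle to a directory
#'
#' Emits a deterministic file set: `counts.tsv` (Table-1-style counts),
#' `profiles.tsv`, `profile_deltas.tsv`, `sjl.tsv`, `pgs.tsv`,
#' `summary.json` (every comparison result, machine-readable) and `run.log`.
#' Writing the same bundle twice yields identical bytes.
#'
#' @param report A `dst_report` from [run_full_analysis()].
#' @param dir Output directory (created if needed).
#' @return Character vector of the files written, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "dst_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  tsv <- function(x, f) utils::write.table(x, p(f), sep = "\t",
                                           row.names = FALSE, quote = FALSE)
  tsv(report$counts, "counts.tsv")
  tsv(as.data.frame(report$profiles), "profiles.tsv")
  tsv(report$profile_deltas, "profile_deltas.tsv")
  tsv(report$sjl$records, "sjl.tsv")
  tsv(as.data.frame(report$pgs), "pgs.tsv")

  comp_json <- function(cr) list(
    statistic = unname(cr$statistic), statistic_kind = cr$statistic_kind,
    p_value = cr$p_value, estimate = as.list(cr$estimate),
    sem = as.list(cr$sem), n = as.list(cr$n))
  ww_json <- function(ww) list(
    f_statistic = unname(ww$statistic), df1 = unname(ww$parameter["df1"]),
    df2 = unname(ww$parameter["df2"]), p_value = ww$p.value,
    kappa_hat = ww$kappa_hat, correction_factor = ww$correction_factor,
    group_mean_hours = as.list(ww$estimate))
  summary <- list(
    asleep_time = lapply(report$asleep_time, comp_json),
    midpoint_tests = lapply(report$midpoint_tests, ww_json),
    social_jetlag = lapply(report$sjl$comparisons, comp_json),
    n_sjl_excluded = report$sjl$n_excluded
  )
  jsonlite::write_json(summary, p("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  writeLines(report$log, p("run.log"))
  invisible(p(c("counts.tsv", "profiles.tsv", "profile_deltas.tsv",
                "sjl.tsv", "pgs.tsv", "summary.json", "run.log")))
}
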