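#' Configuration for the synthetic DST cohort generator
#'
#' Bundles every tunable of the synthetic study: genotype dimensions, the
#' strength of the true additive genetic effect on sleep midpoint, the sleep
#' schedule's population parameters, the DST transition date, the
#' group-dependent post-DST adjustment dynamics, and the dropout rates. All
#' randomness downstream flows from the single `seed`, so identical
#' configurations give byte-identical outputs.
#'
#' @param n_subjects,n_variants Cohort dimensions (positive integers).
#' @param maf_range Range (within `(0, 0.5]`) from which each variant's
#'   effect-allele frequency is drawn uniformly.
#' @param effect_size_sd SD of the per-variant effect sizes, in minutes of
#'   sleep-midpoint shift per effect allele.
#' @param genetic_signal_fraction Fraction (in `[0, 1]`) of latent-midpoint
#'   variance explained by the true polygenic score.
#' @param baseline_midpoint Population mean sleep midpoint, clock hours.
#' @param midpoint_sd SD in minutes of the non-genetic (residual)
#'   between-subject midpoint variation.
#' @param mean_sleep_duration,duration_sd Mean and SD of nightly minutes
#'   asleep.
#' @param onset_jitter_sd Night-to-night within-subject timing jitter SD,
#'   minutes.
#' @param dst_date The Sunday the clocks advance.
#' @param adjust_days_morning Days over which the post-DST delay decays
#'   (piecewise linearly) — to zero for the morning tertile, to
#'   `persistent_delay_evening` for the evening tertile (the middle tertile
#'   decays to half the persistent delay).
#' @param persistent_delay_evening Residual post-DST delay, in minutes, that
#'   the evening tertile retains after re-entrainment would be complete.
#' @param free_night_delay Minutes by which every subject's sleep is delayed
#'   on free (Friday/Saturday) nights, in both weeks.
#' @param short_event_rate Probability a night's bout is truncated to an
#'   asleep duration uniform in `[60, 235]` minutes (guaranteed to fail the
#'   four-hour filter).
#' @param missing_night_rate Probability a subject-night yields no event.
#' @param mhc_variant_fraction Fraction of variants placed inside the MHC
#'   exclusion window (chromosome 6, 25-34 Mb).
#' @param seed Integer seed driving all generation.
#' @return An object of class `"cohort_config"`.
#' @export
cohort_config <- function(n_subjects = 800,
                          n_variants = 600,
                          maf_range = c(0.05, 0.5),
                          effect_size_sd = 1.5,
                          genetic_signal_fraction = 0.3,
                          baseline_midpoint = 3.4,
                          midpoint_sd = 40,
                          mean_sleep_duration = 410,
                          duration_sd = 40,
                          onset_jitter_sd = 20,
                          dst_date = as.Date("2019-03-10"),
                          adjust_days_morning = 2,
                          persistent_delay_evening = 45,
                          free_night_delay = 50,
                          short_event_rate = 0.08,
                          missing_night_rate = 0.05,
                          mhc_variant_fraction = 0.05,
                          seed = 1L) {
  stopifnot(n_subjects >= 1, n_variants >= 1,
            length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            effect_size_sd >= 0,
            genetic_signal_fraction >= 0, genetic_signal_fraction <= 1,
            midpoint_sd >= 0, mean_sleep_duration > 0, duration_sd >= 0,
            onset_jitter_sd >= 0,
            adjust_days_morning >= 0, persistent_delay_evening >= 0,
            free_night_delay >= 0,
            short_event_rate >= 0, short_event_rate <= 1,
            missing_night_rate >= 0, missing_night_rate <= 1,
            mhc_variant_fraction >= 0, mhc_variant_fraction <= 1)
  dst_date <- as.Date(dst_date)
  if (day_index(dst_date) != 0L)
    stop("cohort_config: dst_date must be a Sunday")
  structure(as.list(environment()), class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat("  subjects:", x$n_subjects, " variants:", x$n_variants, "\n")
  cat("  genetic signal fraction:", x$genetic_signal_fraction, "\n")
  cat("  DST date:", format(x$dst_date), "\n")
  cat("  adjustment: morning", x$adjust_days_morning, "days; evening keeps",
      x$persistent_delay_evening, "min\n")
  invisible(x)
}

subject_ids <- function(n) sprintf("S%04d", seq_len(n))

#' Generate a synthetic genotype set
#'
#' Draws each variant's effect-allele frequency uniformly from `maf_range`,
#' dosages from Hardy-Weinberg proportions at that frequency, and per-variant
#' effect sizes from `N(0, effect_size_sd^2)`. A fraction
#' `mhc_variant_fraction` of variants is placed inside the MHC window on
#' chromosome 6; the rest are scattered over the autosomes. The variant
#' table's `maf` column holds the empirical (observed) minor allele
#' frequency.
#'
#' @param config A [cohort_config()].
#' @return A [genotype_set()].
#' @export
generate_genotypes <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_subjects
  m <- config$n_variants
  p <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  dos <- vapply(p, function(pp) stats::rbinom(n, 2L, pp), numeric(n))
  if (n == 1L) dos <- matrix(dos, nrow = 1L)
  s <- if (config$effect_size_sd == 0) rep(0, m) else
    stats::rnorm(m, 0, config$effect_size_sd)

  n_mhc <- round(config$mhc_variant_fraction * m)
  in_mhc <- seq_len(m) %in% sample.int(m, n_mhc)
  chrom <- as.character(sample.int(22L, m, replace = TRUE))
  chrom[in_mhc] <- "6"
  pos <- sample.int(2.4e8, m, replace = TRUE)
  pos[in_mhc] <- 25e6 + sample.int(9e6, n_mhc, replace = TRUE) - 1L
  alleles <- c("A", "C", "G", "T")
  ea <- sample(alleles, m, replace = TRUE)
  oa <- vapply(ea, function(a) sample(setdiff(alleles, a), 1L), character(1))

  obs_af <- colSums(dos) / (2 * n)
  variants <- data.frame(
    variant_id = sprintf("rs%06d", seq_len(m)),
    chrom = chrom, pos = pos,
    effect_allele = ea, other_allele = oa,
    effect_size = s, maf = minor_af(obs_af),
    stringsAsFactors = FALSE
  )
  genotype_set(dos, variants, subject_ids(n))
}

#' Generate latent chronotypes from a genotype set
#'
#' The latent sleep midpoint of each subject is
#' `baseline_midpoint + a * z + noise`, where `z` is the standardized true
#' polygenic score (all variants, true effect sizes), the noise is Gaussian
#' with SD `midpoint_sd` minutes, and the scale
#' `a = (midpoint_sd/60) * sqrt(f / (1 - f))` is chosen so that the squared
#' correlation between score and latent midpoint equals
#' `f = genetic_signal_fraction` in expectation. At `f = 1` the midpoint is
#' the exact noise-free affine image of the score (scaled by the raw score's
#' own SD in hours).
#'
#' @param genotypes A [genotype_set()] from [generate_genotypes()].
#' @param config The matching [cohort_config()].
#' @return Named numeric vector of latent midpoints in clock hours, with
#'   attribute `"true_score_z"` holding the standardized true score.
#' @export
generate_latent_chronotype <- function(genotypes, config) {
  stopifnot(inherits(genotypes, "genotype_set"),
            inherits(config, "cohort_config"))
  f <- config$genetic_signal_fraction
  if (f < 0 || f > 1)
    stop("generate_latent_chronotype: genetic_signal_fraction must be in [0, 1]")
  set.seed(config$seed + 1L)
  raw <- drop(genotypes$dosages %*% genotypes$variants$effect_size)
  n <- length(raw)
  sd_raw <- stats::sd(raw)
  z <- if (sd_raw > 0) (raw - mean(raw)) / sd_raw else rep(0, n)
  sigma_h <- config$midpoint_sd / 60
  if (f == 1) {
    latent <- config$baseline_midpoint + (raw - mean(raw)) / 60
  } else {
    a <- sigma_h * sqrt(f / (1 - f))
    latent <- config$baseline_midpoint + a * z + stats::rnorm(n, 0, sigma_h)
  }
  names(latent) <- genotypes$subjects
  attr(latent, "true_score_z") <- stats::setNames(z, genotypes$subjects)
  latent
}

# post-DST delay (minutes) carried on night `days_since` (0 = the transition
# Sunday night) by a subject of the given tertile: piecewise-linear decay
# from the full skipped hour to the group's persistent residual.
post_dst_delay <- function(days_since, group, config) {
  target <- switch(as.character(group),
                   morning = 0,
                   middle = config$persistent_delay_evening / 2,
                   evening = config$persistent_delay_evening)
  frac <- if (config$adjust_days_morning <= 0) 0 else
    pmax(0, 1 - days_since / config$adjust_days_morning)
  ifelse(days_since < 0, 0, round(target + (60 - target) * frac))
}

#' Generate the synthetic sleep-event table
#'
#' Produces one candidate bout per subject for each of the 15 nights from the
#' Saturday eight days before the transition through the Saturday after it,
#' centred on the subject's latent midpoint with night-level jitter. Free
#' (Friday/Saturday) nights are delayed by `free_night_delay` for everyone.
#' From the transition Sunday on, each night carries the group-dependent
#' post-DST delay of [cohort_config()]: on free nights the whole bout shifts;
#' on work nights only the onset is delayed, the offset being pinned by the
#' work schedule, so minutes asleep shrink by the delay. Bouts are truncated
#' short with probability `short_event_rate` and nights dropped with
#' probability `missing_night_rate`.
#'
#' Timestamps are emitted in local wall-clock time. The bout of the Saturday
#' night preceding the transition spans the 02:00 clock advance: any of its
#' timestamps falling at or after the transition instant is emitted one hour
#' ahead, so the wall-clock span exceeds the true span by the skipped hour
#' while `minutes_asleep`/`minutes_in_bed` keep the true elapsed values, as a
#' wearable device reports them.
#'
#' @param latent_midpoints Named vector from [generate_latent_chronotype()].
#' @param tertile_labels Factor of `morning`/`middle`/`evening` labels, same
#'   order as `latent_midpoints`.
#' @param config The matching [cohort_config()].
#' @return Data frame with columns `subject_id`, `start`, `end` (`POSIXct`),
#'   `minutes_asleep`, `minutes_in_bed`.
#' @export
generate_sleep_schedule <- function(latent_midpoints, tertile_labels, config) {
  stopifnot(inherits(config, "cohort_config"),
            length(latent_midpoints) == length(tertile_labels))
  dst <- config$dst_date
  if (day_index(dst) != 0L)
    stop("generate_sleep_schedule: dst_date must be a Sunday")
  set.seed(config$seed + 2L)

  n <- length(latent_midpoints)
  ids <- names(latent_midpoints) %||% subject_ids(n)
  nights <- seq(dst - 8, dst + 6, by = "day")
  k <- length(nights)

  # subject-major grid; all draws made up-front in fixed order
  subj <- rep(seq_len(n), each = k)
  night <- rep(nights, times = n)
  N <- n * k
  u_miss <- stats::runif(N)
  jitter <- stats::rnorm(N, 0, config$onset_jitter_sd / 60)
  dur <- round(pmin(pmax(
    stats::rnorm(N, config$mean_sleep_duration, config$duration_sd),
    250), 720))
  u_short <- stats::runif(N)
  short_dur <- round(stats::runif(N, 60, 235))

  keep <- u_miss >= config$missing_night_rate
  ds <- as.integer(night - dst)
  wd <- day_index(night)
  free <- wd %in% c(5L, 6L)
  grp <- as.character(tertile_labels)[subj]

  delay <- numeric(N)
  post <- ds >= 0L
  for (g in c("morning", "middle", "evening")) {
    sel <- post & grp == g
    delay[sel] <- post_dst_delay(ds[sel], g, config)
  }

  midpoint_h <- latent_midpoints[subj] + jitter +
    ifelse(free, config$free_night_delay / 60, 0)
  asleep <- dur
  in_bed <- asleep + 15L
  onset_min <- round((midpoint_h - in_bed / 120) * 60)
  offset_min <- onset_min + in_bed

  shift_all <- post & free
  onset_min[shift_all] <- onset_min[shift_all] + delay[shift_all]
  offset_min[shift_all] <- offset_min[shift_all] + delay[shift_all]

  shift_onset <- post & !free & delay > 0
  d_eff <- pmin(delay, asleep - 61)  # keep the bout non-degenerate
  onset_min[shift_onset] <- onset_min[shift_onset] + d_eff[shift_onset]
  asleep[shift_onset] <- asleep[shift_onset] - d_eff[shift_onset]
  in_bed[shift_onset] <- in_bed[shift_onset] - d_eff[shift_onset]

  short <- u_short < config$short_event_rate
  asleep[short] <- short_dur[short]
  in_bed[short] <- asleep[short] + 15L
  offset_min <- onset_min + in_bed

  midnight_next <- as.POSIXct(paste0(format(night + 1), " 00:00:00"),
                              tz = "UTC")
  start <- midnight_next + onset_min * 60
  end <- midnight_next + offset_min * 60

  # wall-clock emission across the 02:00 spring-forward instant
  transition <- as.POSIXct(paste0(format(dst), " 02:00:00"), tz = "UTC")
  on_dst_night <- night == (dst - 1)
  start[on_dst_night & start >= transition] <-
    start[on_dst_night & start >= transition] + 3600
  end[on_dst_night & end >= transition] <-
    end[on_dst_night & end >= transition] + 3600

  out <- data.frame(subject_id = ids[subj],
                    start = start, end = end,
                    minutes_asleep = as.integer(asleep),
                    minutes_in_bed = as.integer(in_bed),
                    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Generate a complete synthetic study
#'
#' Runs [generate_genotypes()], [generate_latent_chronotype()] and
#' [generate_sleep_schedule()] in sequence. Generation-side tertiles are
#' taken from the TRUE standardized score; the analysis pipeline re-derives
#' its own tertiles from the estimated polygenic score, so agreement between
#' the two labelings is itself a testable property.
#'
#' @param config A [cohort_config()].
#' @return Object of class `"synthetic_cohort"`: list with `genotypes`,
#'   `latent_midpoints`, `true_groups`, `events` and `config`.
#' @export
simulate_cohort <- function(config = cohort_config()) {
  genotypes <- generate_genotypes(config)
  latent <- generate_latent_chronotype(genotypes, config)
  true_groups <- assign_tertiles(attr(latent, "true_score_z"))
  events <- generate_sleep_schedule(latent, true_groups, config)
  structure(list(genotypes = genotypes, latent_midpoints = latent,
                 true_groups = true_groups, events = events, config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic DST cohort:", x$config$n_subjects, "subjects,",
      nrow(x$events), "sleep events around", format(x$config$dst_date), "\n")
  invisible(x)
}
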