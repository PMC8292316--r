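# Pre/post-DST comparisons: time asleep, daily onset/offset profiles,
# midpoint distributions by chronotype group, and social jet lag.

event_midpoint_hours <- function(events) {
  circular_midpoint(time_of_day(events$start), time_of_day(events$end))
}

comparison_result <- function(statistic, kind, p_value, estimate, sem, n,
                              label) {
  structure(list(statistic = statistic, statistic_kind = kind,
                 p_value = p_value, estimate = estimate, sem = sem, n = n,
                 label = label),
            class = "dst_comparison")
}

#' @export
print.dst_comparison <- function(x, ...) {
  cat(x$label, "\n", sep = "")
  cells <- paste(sprintf("%s %.2f ± %.2f (n = %d)",
                         names(x$estimate), x$estimate, x$sem, x$n),
                 collapse = "; ")
  cat("  ", cells, "\n", sep = "")
  cat(sprintf("  %s = %.4f, p = %.4g\n", x$statistic_kind, x$statistic,
              x$p_value))
  invisible(x)
}

#' Compare minutes asleep before vs after DST, per chronotype group
#'
#' For each of the morning and evening groups, compares the minutes asleep of
#' work-night (by default Sunday-Thursday) nighttime events in the pre-DST
#' window against the post-DST window with a two-sample t-test on linear
#' minutes (durations are not circular quantities). The statistic is oriented
#' after-minus-before, so a post-DST drop in sleep gives a negative t.
#'
#' @param events A classified, duration-filtered, same-weekday-paired event
#'   table.
#' @param groups A `pgs_result` or named label vector.
#' @param weekdays Work-night weekdays entering the comparison.
#' @param var_equal Use the pooled-variance Student t instead of the Welch
#'   default?
#' @return Named list (`morning`, `evening`) of `dst_comparison` objects with
#'   before/after means, SEMs (`sd/sqrt(n)`) and cell sizes.
#' @export
asleep_time_comparison <- function(events, groups,
                                   weekdays = c("Sunday", "Monday", "Tuesday",
                                                "Wednesday", "Thursday"),
                                   var_equal = FALSE) {
  grp <- group_lookup(groups)
  ev_grp <- grp[as.character(events$subject_id)]
  base <- events$is_night &
    as.character(events$assigned_weekday) %in% weekdays
  out <- list()
  for (g in c("morning", "evening")) {
    vals <- function(window) {
      sel <- base & !is.na(ev_grp) & ev_grp == g & events$dst_week == window
      events$minutes_asleep[sel]
    }
    before <- vals("before")
    after <- vals("after")
    if (length(before) < 2L || length(after) < 2L)
      stop("asleep_time_comparison: insufficient data in cell (", g,
           ", ", if (length(before) < 2L) "before" else "after", ")")
    tt <- stats::t.test(after, before, var.equal = var_equal)
    out[[g]] <- comparison_result(
      statistic = unname(tt$statistic), kind = "t",
      p_value = tt$p.value,
      estimate = c(before = mean(before), after = mean(after)),
      sem = c(before = stats::sd(before) / sqrt(length(before)),
              after = stats::sd(after) / sqrt(length(after))),
      n = c(before = length(before), after = length(after)),
      label = paste0("Minutes asleep on work nights, ", g,
                     " group (after - before DST)"))
  }
  out
}

#' Welch two-sample t-test from summary statistics
#'
#' Reconstructs the Welch t statistic, Welch-Satterthwaite degrees of freedom
#' and two-sided p-value from group means, standard errors of the mean and
#' sample sizes — useful for checking published comparisons when only
#' summaries are printed.
#'
#' @param m1,m2 Group means.
#' @param sem1,sem2 Standard errors of the mean (`sd/sqrt(n)`).
#' @param n1,n2 Sample sizes.
#' @return List with `t`, `df` and `p_value`; `t` is oriented `m1 - m2`.
#' @export
welch_t_summary <- function(m1, sem1, n1, m2, sem2, n2) {
  stopifnot(n1 >= 2, n2 >= 2, sem1 >= 0, sem2 >= 0)
  v <- sem1^2 + sem2^2
  t <- (m1 - m2) / sqrt(v)
  df <- v^2 / (sem1^4 / (n1 - 1) + sem2^4 / (n2 - 1))
  list(t = t, df = df, p_value = 2 * stats::pt(-abs(t), df))
}

#' Circular mean onset/offset/midpoint profiles by group, window and weekday
#'
#' Computes, for each chronotype group (morning/evening), DST window
#' (before/after) and weekday, the circular mean of sleep onset times, offset
#' times and bout midpoints, with the number of contributing events. All
#' time-of-day aggregation is circular; cells with no events are reported
#' with `n = 0` and missing means.
#'
#' @param events A classified, duration-filtered, same-weekday-paired event
#'   table.
#' @param groups A `pgs_result` or named label vector.
#' @return Data frame of class `"profile_table"` with columns `group`,
#'   `window`, `weekday`, `mean_onset`, `mean_offset`, `mean_midpoint`
#'   (clock hours) and `n`.
#' @export
daily_profiles <- function(events, groups) {
  grp <- group_lookup(groups)
  ev_grp <- grp[as.character(events$subject_id)]
  grid <- expand.grid(weekday = DAY_NAMES, window = c("before", "after"),
                      group = c("morning", "evening"),
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    sel <- events$is_night & !is.na(ev_grp) &
      ev_grp == grid$group[i] &
      events$dst_week == grid$window[i] &
      as.character(events$assigned_weekday) == grid$weekday[i]
    n <- sum(sel)
    if (n == 0L)
      return(data.frame(grid[i, ], mean_onset = NA_real_,
                        mean_offset = NA_real_, mean_midpoint = NA_real_,
                        n = 0L))
    onset <- circular_mean(hours_to_angle(time_of_day(events$start[sel])))
    offset <- circular_mean(hours_to_angle(time_of_day(events$end[sel])))
    mid <- circular_mean(hours_to_angle(event_midpoint_hours(events[sel, ])))
    data.frame(grid[i, ], mean_onset = onset$mean_hours,
               mean_offset = offset$mean_hours,
               mean_midpoint = mid$mean_hours, n = n)
  })
  out <- do.call(rbind, rows)[, c("group", "window", "weekday", "mean_onset",
                                  "mean_offset", "mean_midpoint", "n")]
  rownames(out) <- NULL
  class(out) <- c("profile_table", "data.frame")
  out
}

#' After-minus-before differences of a profile table, in wrapped minutes
#'
#' @param profiles A `"profile_table"` from [daily_profiles()].
#' @return Data frame with columns `group`, `weekday` and the signed wrapped
#'   after-minus-before differences `d_onset`, `d_offset`, `d_midpoint` in
#'   minutes (`(-720, 720]`).
#' @export
profile_differences <- function(profiles) {
  before <- profiles[profiles$window == "before", ]
  after <- profiles[profiles$window == "after", ]
  key <- c("group", "weekday")
  m <- merge(before, after, by = key, suffixes = c("_b", "_a"))
  out <- data.frame(
    m[key],
    d_onset = wrapped_diff_minutes(m$mean_onset_b, m$mean_onset_a),
    d_offset = wrapped_diff_minutes(m$mean_offset_b, m$mean_offset_a),
    d_midpoint = wrapped_diff_minutes(m$mean_midpoint_b, m$mean_midpoint_a)
  )
  out[order(match(out$group, c("morning", "evening")),
            match(out$weekday, DAY_NAMES)), , drop = FALSE]
}

#' Watson-Williams test on pre-DST sleep midpoints, morning vs evening
#'
#' Uses every retained nighttime event whose assigned night falls strictly
#' before the transition Sunday (not just the final pre-DST week, and without
#' the same-weekday pairing rule), restricted to work or free nights under
#' the profile convention (work = Sunday-Thursday, free = Friday-Saturday).
#' Bout midpoints are computed on the 24-h circle and the morning and evening
#' groups compared with [watson_williams()].
#'
#' @param events A classified event table (unpaired). The four-hour retention
#'   rule is applied here when `apply_duration_filter` is `TRUE`.
#' @param groups A `pgs_result` or named label vector.
#' @param night_class `"work"` or `"free"`.
#' @param min_minutes Retention threshold in minutes asleep.
#' @param apply_duration_filter Apply the retention rule?
#' @return A `watson_williams` result; `estimate` holds the two group mean
#'   midpoints as clock hours.
#' @export
midpoint_distribution_test <- function(events, groups,
                                       night_class = c("work", "free"),
                                       min_minutes = 240,
                                       apply_duration_filter = TRUE) {
  night_class <- match.arg(night_class)
  dst_date <- attr(events, "dst_date")
  if (is.null(dst_date))
    stop("midpoint_distribution_test: events must come from classify_events()")
  grp <- group_lookup(groups)
  ev <- label_work_free(events, "profile")
  ev_grp <- grp[as.character(ev$subject_id)]
  sel <- ev$is_night & ev$assigned_night < dst_date &
    !is.na(ev$is_work_night) & ev$is_work_night == (night_class == "work")
  if (apply_duration_filter) sel <- sel & ev$minutes_asleep >= min_minutes
  mids <- list(
    morning = event_midpoint_hours(ev[sel & !is.na(ev_grp) &
                                        ev_grp == "morning", ]),
    evening = event_midpoint_hours(ev[sel & !is.na(ev_grp) &
                                        ev_grp == "evening", ])
  )
  if (any(lengths(mids) < 2L))
    stop("midpoint_distribution_test: a group has fewer than 2 events")
  watson_williams(lapply(mids, hours_to_angle))
}

#' Per-subject social jet lag and its pre/post-DST comparison
#'
#' Social jet lag (SJL) is the difference between a subject's mean free-night
#' sleep midpoint and mean work-night sleep midpoint, here under the SJL
#' convention: work nights Monday-Thursday, free nights Friday-Saturday
#' (Sunday unlabelled). A subject enters a window if it has at least one
#' work-night and at least one free-night event there; subjects need not
#' appear in both windows. Midpoints are averaged circularly per subject and
#' the difference is the signed wrapped free-minus-work gap in minutes. Per
#' group, before vs after windows are compared by a two-sample t-test on SJL
#' minutes (after-minus-before orientation).
#'
#' @param events A classified, duration-filtered (but not paired) event
#'   table.
#' @param groups A `pgs_result` or named label vector.
#' @param var_equal Pooled-variance t instead of Welch?
#' @return List with `records` (data frame: `subject_id`, `window`,
#'   `work_midpoint`, `free_midpoint`, `sjl_minutes`, `group`),
#'   `comparisons` (per-group `dst_comparison`), and `n_excluded` (subject-
#'   windows failing the one-work/one-free rule).
#' @export
social_jetlag <- function(events, groups, var_equal = FALSE) {
  grp <- group_lookup(groups)
  ev <- label_work_free(events, "sjl")
  ev <- ev[ev$is_night & !is.na(ev$is_work_night) &
             ev$dst_week %in% c("before", "after"), , drop = FALSE]
  ev$midpoint <- event_midpoint_hours(ev)

  recs <- list()
  n_excluded <- 0L
  for (window in c("before", "after")) {
    evw <- ev[ev$dst_week == window, , drop = FALSE]
    for (sid in unique(as.character(evw$subject_id))) {
      es <- evw[evw$subject_id == sid, , drop = FALSE]
      work <- es$midpoint[es$is_work_night]
      free <- es$midpoint[!es$is_work_night]
      if (length(work) < 1L || length(free) < 1L) {
        n_excluded <- n_excluded + 1L
        next
      }
      wm <- circular_mean(hours_to_angle(work))$mean_hours
      fm <- circular_mean(hours_to_angle(free))$mean_hours
      recs[[length(recs) + 1L]] <- data.frame(
        subject_id = sid, window = window,
        work_midpoint = wm, free_midpoint = fm,
        sjl_minutes = wrapped_diff_minutes(wm, fm),
        group = unname(grp[sid]) %||% NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  records <- if (length(recs)) do.call(rbind, recs) else
    data.frame(subject_id = character(), window = character(),
               work_midpoint = numeric(), free_midpoint = numeric(),
               sjl_minutes = numeric(), group = character())

  comparisons <- list()
  for (g in c("morning", "evening")) {
    before <- records$sjl_minutes[records$window == "before" &
                                    !is.na(records$group) &
                                    records$group == g]
    after <- records$sjl_minutes[records$window == "after" &
                                   !is.na(records$group) &
                                   records$group == g]
    if (length(before) < 2L || length(after) < 2L) {
      comparisons[[g]] <- NULL
      next
    }
    tt <- stats::t.test(after, before, var.equal = var_equal)
    comparisons[[g]] <- comparison_result(
      statistic = unname(tt$statistic), kind = "t",
      p_value = tt$p.value,
      estimate = c(before = mean(before), after = mean(after)),
      sem = c(before = stats::sd(before) / sqrt(length(before)),
              after = stats::sd(after) / sqrt(length(after))),
      n = c(before = length(before), after = length(after)),
      label = paste0("Social jet lag (min), ", g,
                     " group (after - before DST)"))
  }
  list(records = records, comparisons = comparisons,
       n_excluded = n_excluded)
}

#' Run the complete DST chronotype analysis
#'
#' End-to-end orchestration: genotype QC, polygenic scoring and tertile
#' grouping; sleep-event classification against the DST windows; the
#' four-hour retention filter and same-weekday pairing; and the four result
#' layers — the Table-1-style counts table, the work-night time-asleep
#' comparison, the daily onset/offset profiles with their wrapped
#' differences, the pre-DST midpoint distribution tests, and the social jet
#' lag comparison.
#'
#' @param events Sleep events: a data frame or a path to a CSV written by
#'   [write_sleep_events()].
#' @param genotypes A [genotype_set()] or a length-2 character vector of
#'   paths (dosage TSV, variant TSV) as written by [write_genotypes()].
#' @param config A [run_config()].
#' @return Object of class `"dst_report"`.
#' @export
run_full_analysis <- function(events, genotypes, config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  if (is.character(events)) events <- read_sleep_events(events)
  if (is.character(genotypes))
    genotypes <- read_genotypes(genotypes[1], genotypes[2])

  log <- character()
  say <- function(...) log <<- c(log, paste0(...))

  pgs <- pgs_pipeline(genotypes, config$qc)
  ql <- attr(pgs, "qc_log")
  say("pgs: ", paste(ql$step, ql$removed, sep = "=", collapse = ", "),
      "; variants scored=", attr(pgs, "n_variants_used"),
      "; subjects scored=", nrow(pgs))

  classified <- classify_events(events, config$dst_date)
  say("classify: ", nrow(classified), " events, ",
      sum(classified$is_night), " nighttime")
  filtered <- filter_min_duration(classified, config$min_event_minutes)
  say("duration filter (<", config$min_event_minutes, " min asleep): ",
      attr(filtered, "n_dropped_short"), " dropped")
  paired <- pair_same_weekday(filtered)
  say("same-weekday pairing: ", attr(paired, "n_dropped_unpaired"),
      " dropped, ", nrow(paired), " retained")

  counts <- tabulate_counts(classified, pgs, config$min_event_minutes)
  asleep <- asleep_time_comparison(paired, pgs,
                                   var_equal = config$var_equal)
  profiles <- daily_profiles(paired, pgs)
  deltas <- profile_differences(profiles)
  mid_tests <- list(
    work = midpoint_distribution_test(filtered, pgs, "work",
                                      config$min_event_minutes,
                                      apply_duration_filter = FALSE),
    free = midpoint_distribution_test(filtered, pgs, "free",
                                      config$min_event_minutes,
                                      apply_duration_filter = FALSE)
  )
  sjl <- social_jetlag(filtered, pgs, var_equal = config$var_equal)
  say("sjl: ", nrow(sjl$records), " subject-windows, ",
      sjl$n_excluded, " excluded by the one-work/one-free rule")

  structure(
    list(pgs = pgs, counts = counts, asleep_time = asleep,
         profiles = profiles, profile_deltas = deltas,
         midpoint_tests = mid_tests, sjl = sjl,
         log = log, config = config),
    class = "dst_report"
  )
}

#' @export
print.dst_report <- function(x, ...) {
  cat("DST chronotype analysis report\n")
  cat("==============================\n")
  cat("Groups:", paste(names(table(x$pgs$group)),
                       table(x$pgs$group), collapse = ", "), "\n\n")
  for (g in names(x$asleep_time)) print(x$asleep_time[[g]])
  cat("\nPre-DST midpoint tests (morning vs evening):\n")
  for (nc in names(x$midpoint_tests)) {
    ww <- x$midpoint_tests[[nc]]
    cat(sprintf("  %s nights: means %s vs %s, F = %.3f, p = %.3g\n", nc,
                format_clock(ww$estimate[1]), format_clock(ww$estimate[2]),
                ww$statistic, ww$p.value))
  }
  cat("\nSocial jet lag:\n")
  for (g in names(x$sjl$comparisons)) print(x$sjl$comparisons[[g]])
  invisible(x)
}

#' @export
summary.dst_report <- function(object, ...) {
  cat(object$log, sep = "\n")
  invisible(object)
}
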