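#' Pre- and post-DST analysis windows
#'
#' The pre-DST week runs from the Saturday eight days before the transition
#' Sunday through the Friday before it; the post-DST week runs from the
#' transition Sunday through the following Saturday. Each window therefore
#' contains each weekday exactly once, and the Saturday night immediately
#' before the transition belongs to neither window. For the 2019 spring
#' transition (2019-03-10) this gives 2019-03-02..2019-03-08 and
#' 2019-03-10..2019-03-16.
#'
#' @param dst_date The Sunday on which clocks advance (`Date` or string).
#' @return List with `before` and `after`, each a vector of the window's
#'   first and last assigned-night dates.
#' @export
dst_windows <- function(dst_date) {
  dst_date <- as.Date(dst_date)
  if (day_index(dst_date) != 0L)
    stop("dst_windows: dst_date must be the transition Sunday")
  list(before = c(start = dst_date - 8, end = dst_date - 2),
       after = c(start = dst_date, end = dst_date + 6))
}

#' Classify raw sleep events
#'
#' Annotates each device-recorded sleep bout with:
#' * `is_night` — whether the bout started between 18:00 (inclusive) and
#'   06:00 (exclusive);
#' * `assigned_weekday` / `assigned_night` — the evening the bout is
#'   attributed to: the calendar day of the start, shifted back one day when
#'   the start falls in `[00:00, 06:00)`, so a bout starting Monday 01:30 is
#'   a Sunday nighttime event;
#' * `dst_week` — `before`, `after` or `outside`, by [dst_windows()].
#'
#' @param events Data frame with columns `subject_id`, `start`, `end`
#'   (ISO-8601 local wall-clock timestamps or `POSIXct`), `minutes_asleep`,
#'   `minutes_in_bed`.
#' @param dst_date The transition Sunday.
#' @return The input with columns `is_night`, `assigned_weekday` (factor
#'   Sunday..Saturday), `assigned_night` (`Date`) and `dst_week` (factor
#'   before/after/outside) added; class `"classified_events"` prepended.
#' @export
classify_events <- function(events, dst_date) {
  need <- c("subject_id", "start", "end", "minutes_asleep", "minutes_in_bed")
  miss <- setdiff(need, names(events))
  if (length(miss))
    stop("classify_events: missing columns: ", paste(miss, collapse = ", "))
  events <- as.data.frame(events)

  start <- if (inherits(events$start, "POSIXct")) events$start else
    parse_ts(events$start)
  end <- if (inherits(events$end, "POSIXct")) events$end else
    parse_ts(events$end)
  bad_parse <- which(is.na(start) | is.na(end))
  if (length(bad_parse))
    stop("classify_events: unparseable timestamp in rows ",
         paste(utils::head(bad_parse, 5L), collapse = ", "))
  bad_order <- which(end <= start)
  if (length(bad_order))
    stop("classify_events: end not after start in rows ",
         paste(utils::head(bad_order, 5L), collapse = ", "))

  tod <- time_of_day(start)
  events$start <- start
  events$end <- end
  events$is_night <- tod >= 18 | tod < 6

  start_date <- as.Date(start, tz = "UTC")
  night <- start_date - as.integer(tod < 6)
  events$assigned_night <- night
  events$assigned_weekday <- factor(day_name(night), levels = DAY_NAMES)

  w <- dst_windows(dst_date)
  wk <- rep("outside", nrow(events))
  wk[night >= w$before["start"] & night <= w$before["end"]] <- "before"
  wk[night >= w$after["start"] & night <= w$after["end"]] <- "after"
  events$dst_week <- factor(wk, levels = c("before", "after", "outside"))
  attr(events, "dst_date") <- as.Date(dst_date)
  class(events) <- c("classified_events", "data.frame")
  events
}

#' Drop sleep events shorter than a minimum asleep duration
#'
#' Bouts with fewer than `min_minutes` minutes asleep (strictly less; a bout
#' of exactly `min_minutes` is kept) are removed from the analyzable set —
#' they typically reflect interrupted sleep, e.g. a subject called into work
#' overnight. The filter uses minutes asleep, not the wall-clock span, which
#' is distorted on the transition night.
#'
#' @param events A classified event table.
#' @param min_minutes Minimum minutes asleep; default 240 (four hours).
#' @return The retained rows, with attribute `"n_dropped_short"`.
#' @export
filter_min_duration <- function(events, min_minutes = 240) {
  if (!is.numeric(min_minutes) || min_minutes < 0)
    stop("filter_min_duration: min_minutes must be non-negative")
  keep <- events$minutes_asleep >= min_minutes
  out <- events[keep, , drop = FALSE]
  attr(out, "dst_date") <- attr(events, "dst_date")
  attr(out, "n_dropped_short") <- sum(!keep)
  class(out) <- class(events)
  out
}

#' Keep only same-weekday-paired events across the two DST windows
#'
#' For each weekday independently, a subject's nighttime events on that
#' weekday are kept only if the subject has at least one retained nighttime
#' event on that same weekday in **both** the pre- and post-DST windows. This
#' balances shift-schedule structure across the two weeks: a subject seen
#' only the Monday before (but not the Monday after) contributes nothing to
#' the Monday analysis. Events outside the two windows, and daytime events,
#' are dropped here.
#'
#' @param events A classified (and typically duration-filtered) event table.
#' @return The paired subset, with attribute `"n_dropped_unpaired"` counting
#'   rows removed by the pairing rule (not those outside the windows).
#' @export
pair_same_weekday <- function(events) {
  inwin <- events$is_night & events$dst_week %in% c("before", "after")
  ev <- events[inwin, , drop = FALSE]
  if (nrow(ev) == 0L) {
    attr(ev, "n_dropped_unpaired") <- 0L
    return(ev)
  }
  key <- paste(ev$subject_id, ev$assigned_weekday, sep = "\r")
  has_before <- tapply(ev$dst_week == "before", key, any)
  has_after <- tapply(ev$dst_week == "after", key, any)
  ok_keys <- names(which(has_before & has_after))
  keep <- key %in% ok_keys
  out <- ev[keep, , drop = FALSE]
  attr(out, "dst_date") <- attr(events, "dst_date")
  attr(out, "n_dropped_unpaired") <- sum(!keep)
  class(out) <- class(events)
  out
}

#' Label nights as work or free
#'
#' Two conventions are used downstream:
#' * `"profile"` (time-asleep and daily-profile analyses): work nights are
#'   Sunday through Thursday, free nights Friday and Saturday.
#' * `"sjl"` (social jet lag): work nights are Monday through Thursday, free
#'   nights Friday and Saturday; Sunday nights are left unlabelled (`NA`).
#'
#' @param events A classified event table.
#' @param convention `"profile"` or `"sjl"`.
#' @return The input with logical column `is_work_night` added (`NA` where a
#'   night is unlabelled under the convention).
#' @export
label_work_free <- function(events, convention = c("profile", "sjl")) {
  convention <- match.arg(convention)
  wd <- as.character(events$assigned_weekday)
  work_days <- if (convention == "profile")
    c("Sunday", "Monday", "Tuesday", "Wednesday", "Thursday") else
      c("Monday", "Tuesday", "Wednesday", "Thursday")
  free_days <- c("Friday", "Saturday")
  lab <- rep(NA, length(wd))
  lab[wd %in% work_days] <- TRUE
  lab[wd %in% free_days] <- FALSE
  events$is_work_night <- lab
  events
}

#' Tabulate nighttime event counts by weekday, window and group
#'
#' Produces the per-weekday breakdown of nighttime sleep events in the two
#' DST windows, for all subjects and for the morning and evening polygenic
#' score groups, with a companion count of events surviving the four-hour
#' retention rule, and a `Total` row equal to the column sums.
#'
#' @param events A classified event table (unfiltered; the retention counts
#'   are computed here from `minutes_asleep`).
#' @param groups Either a `pgs_result` data frame or a named vector/factor of
#'   group labels per subject.
#' @param min_minutes Retention threshold in minutes asleep (default 240).
#' @return Data frame with a `weekday` column (Sunday..Saturday then
#'   `Total`) and, for each window x population, columns
#'   `<window>_<pop>` and `<window>_<pop>_4h`.
#' @export
tabulate_counts <- function(events, groups, min_minutes = 240) {
  grp <- group_lookup(groups)
  ev <- events[events$is_night & events$dst_week %in% c("before", "after"), ,
               drop = FALSE]
  ev_grp <- grp[as.character(ev$subject_id)]
  retained <- ev$minutes_asleep >= min_minutes

  cell <- function(window, pop) {
    sel <- ev$dst_week == window
    if (pop != "all") sel <- sel & !is.na(ev_grp) & ev_grp == pop
    wd <- factor(as.character(ev$assigned_weekday)[sel], levels = DAY_NAMES)
    data.frame(n = as.integer(table(wd)),
               n4h = as.integer(table(wd[retained[sel]])))
  }

  out <- data.frame(weekday = DAY_NAMES, stringsAsFactors = FALSE)
  for (window in c("before", "after"))
    for (pop in c("all", "morning", "evening")) {
      cc <- cell(window, pop)
      out[[paste0(window, "_", pop)]] <- cc$n
      out[[paste0(window, "_", pop, "_4h")]] <- cc$n4h
    }
  add_total_row(out)
}

#' Append a Total row to a counts table
#'
#' Sums every numeric column of a per-weekday counts table into a final row
#' labelled `Total`. Exposed separately so totals can be recomputed for any
#' externally supplied per-weekday breakdown.
#'
#' @param counts Data frame whose first column labels rows (e.g. weekdays)
#'   and whose remaining columns are numeric counts.
#' @return The table with a `Total` row appended (an existing `Total` row is
#'   replaced).
#' @export
add_total_row <- function(counts) {
  counts <- counts[counts[[1]] != "Total", , drop = FALSE]
  tot <- counts[1, , drop = FALSE]
  tot[[1]] <- "Total"
  for (j in seq(2L, ncol(counts)))
    tot[[j]] <- sum(counts[[j]])
  rbind(counts, tot, make.row.names = FALSE)
}

# Normalize a groups argument (pgs_result or named labels) to a named
# character vector subject_id -> label.
group_lookup <- function(groups) {
  if (inherits(groups, "pgs_result") ||
      (is.data.frame(groups) && all(c("subject_id", "group") %in% names(groups)))) {
    out <- as.character(groups$group)
    names(out) <- as.character(groups$subject_id)
  } else {
    if (is.null(names(groups)))
      stop("groups must be a pgs_result or a named vector of labels")
    out <- as.character(groups)
    names(out) <- names(groups)
  }
  out
}
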