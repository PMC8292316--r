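groups2 <- c(m1 = "morning", e1 = "evening")

work_nights_before <- as.Date(c("2019-03-03", "2019-03-04", "2019-03-05"))
work_nights_after <- work_nights_before + 7

test_that("time-asleep comparison matches the closed-form Welch evaluation", {
  ev <- rbind(
    do.call(rbind, Map(function(d, a) make_event("m1", d, 23, a),
                       work_nights_before, c(400, 410, 420))),
    do.call(rbind, Map(function(d, a) make_event("m1", d, 23, a),
                       work_nights_after, c(390, 400, 410))),
    do.call(rbind, Map(function(d, a) make_event("e1", d, 23, a),
                       c(work_nights_before, work_nights_after),
                       rep(c(395, 405, 415), 2)))
  )
  cl <- pair_same_weekday(filter_min_duration(classify_events(ev, DST19)))
  res <- asleep_time_comparison(cl, groups2)

  # morning: after {390,400,410} vs before {400,410,420}; equal variances 100
  expect_equal(res$morning$statistic, -10 / sqrt(100 / 3 + 100 / 3),
               tolerance = 1e-10)
  expect_equal(res$morning$statistic, -1.2247, tolerance = 1e-4)
  tt <- t.test(c(390, 400, 410), c(400, 410, 420))
  expect_equal(res$morning$p_value, tt$p.value, tolerance = 1e-10)
  expect_equal(unname(res$morning$estimate), c(410, 400))
  expect_equal(unname(res$morning$n), c(3L, 3L))
  expect_equal(unname(res$morning$sem), rep(10 / sqrt(3), 2))

  # identical before/after samples: t = 0, p = 1
  expect_equal(res$evening$statistic, 0)
  expect_equal(res$evening$p_value, 1)
})

test_that("Welch reconstruction from summary statistics equals the full-data test", {
  x <- c(390, 400, 410)
  y <- c(400, 410, 420)
  full <- t.test(x, y)
  s <- welch_t_summary(mean(x), sd(x) / sqrt(3), 3, mean(y), sd(y) / sqrt(3), 3)
  expect_equal(s$t, unname(full$statistic), tolerance = 1e-12)
  expect_equal(s$df, unname(full$parameter), tolerance = 1e-12)
  expect_equal(s$p_value, full$p.value, tolerance = 1e-12)
})

test_that("profile cells average circularly: times straddling midnight mean midnight", {
  ev <- rbind(make_event("m1", "2019-03-04", 23.5, 240),
              make_event("m1", "2019-03-04", 0.5, 240),
              make_event("e1", "2019-03-04", 22, 240))
  cl <- classify_events(ev, DST19)
  prof <- daily_profiles(cl, groups2)
  cell <- prof[prof$group == "morning" & prof$window == "before" &
                 prof$weekday == "Monday", ]
  expect_equal(cell$mean_onset, 0, tolerance = 1e-9)
  expect_equal(cell$n, 2L)
  # single-event cell reproduces that event's times
  single <- prof[prof$group == "evening" & prof$window == "before" &
                   prof$weekday == "Monday", ]
  expect_equal(single$mean_onset, 22, tolerance = 1e-9)
  expect_equal(single$mean_offset, 2, tolerance = 1e-9)
  expect_equal(single$mean_midpoint, 0, tolerance = 1e-9)
  # empty cells carry n = 0 and no mean
  expect_true(all(is.na(prof$mean_onset[prof$n == 0])))
})

test_that("social jet lag reproduces hand-evaluated subject records", {
  ev <- rbind(
    # m1, before: four work midpoints at 02:00, two free at 03:00 -> +60
    do.call(rbind, lapply(as.Date(c("2019-03-04", "2019-03-05", "2019-03-06",
                                    "2019-03-07")),
                          function(d) make_event("m1", d, 0, 240))),
    make_event("m1", "2019-03-08", 1, 240),
    make_event("m1", "2019-03-02", 1, 240),
    # e1, before: work midpoints 01:30 and 02:30 (circular mean 02:00),
    # one free at 03:00 -> +60
    make_event("e1", "2019-03-04", 23.5, 240),
    make_event("e1", "2019-03-05", 0.5, 240),
    make_event("e1", "2019-03-08", 1, 240),
    # e1, after: identical work and free midpoints -> 0
    make_event("e1", "2019-03-11", 0, 240),
    make_event("e1", "2019-03-15", 0, 240),
    # m2 fails the one-work/one-free rule (work only)
    make_event("m2", "2019-03-04", 0, 240)
  )
  cl <- classify_events(ev, DST19)
  res <- social_jetlag(cl, c(groups2, m2 = "morning"))
  r <- res$records
  expect_equal(r$sjl_minutes[r$subject_id == "m1" & r$window == "before"], 60,
               tolerance = 1e-9)
  expect_equal(r$work_midpoint[r$subject_id == "e1" & r$window == "before"], 2,
               tolerance = 1e-9)
  expect_equal(r$sjl_minutes[r$subject_id == "e1" & r$window == "before"], 60,
               tolerance = 1e-9)
  expect_equal(r$sjl_minutes[r$subject_id == "e1" & r$window == "after"], 0,
               tolerance = 1e-9)
  expect_false("m2" %in% r$subject_id)
  expect_equal(res$n_excluded, 1L)
})

test_that("wrapped differences stay in (-720, 720] and are antisymmetric", {
  set.seed(21)
  a <- runif(200, 0, 24)
  b <- runif(200, 0, 24)
  d <- wrapped_diff_minutes(a, b)
  expect_true(all(d > -720 & d <= 720))
  swapped <- wrapped_diff_minutes(b, a)
  ok <- abs(d) != 720
  expect_equal(d[ok], -swapped[ok])
  expect_equal(wrapped_diff_minutes(23.5, 0.5), 60)
})

test_that("midpoint test uses all pre-DST nights and returns F = 0 for identical groups", {
  mk <- function(id, onset) rbind(
    make_event(id, "2019-02-25", onset, 400),  # before the pre-DST window
    make_event(id, "2019-03-04", onset + 0.5, 400),
    make_event(id, "2019-03-05", onset - 0.5, 400))
  cl <- classify_events(rbind(mk("m1", 23.5), mk("e1", 23.5)), DST19)
  ww <- midpoint_distribution_test(cl, groups2, "work")
  expect_equal(unname(ww$statistic), 0, tolerance = 1e-9)
  expect_equal(sum(ww$n), 6)  # the outside-window night still contributes

  # post-DST events never enter
  cl2 <- classify_events(rbind(mk("m1", 23.5), mk("e1", 23.5),
                               make_event("e1", "2019-03-12", 20, 400)), DST19)
  ww2 <- midpoint_distribution_test(cl2, groups2, "work")
  expect_equal(sum(ww2$n), 6)
})

test_that("noise-free cohorts recover the configured delays exactly through the full pipeline", {
  cfg <- cohort_config(n_subjects = 30, n_variants = 40,
                       onset_jitter_sd = 0, duration_sd = 0,
                       short_event_rate = 0, missing_night_rate = 0,
                       adjust_days_morning = 2, persistent_delay_evening = 45,
                       seed = 13)
  co <- simulate_cohort(cfg)
  cl <- pair_same_weekday(filter_min_duration(classify_events(co$events,
                                                              cfg$dst_date)))
  prof <- daily_profiles(cl, co$true_groups)
  d <- profile_differences(prof)
  ev_fri <- d[d$group == "evening" & d$weekday == "Friday", ]
  expect_equal(ev_fri$d_onset, 45, tolerance = 1e-6)
  expect_equal(ev_fri$d_offset, 45, tolerance = 1e-6)
  mo <- d[d$group == "morning" &
            d$weekday %in% c("Tuesday", "Wednesday", "Thursday", "Friday"), ]
  expect_true(all(abs(mo$d_onset) < 1e-6))
})

test_that("a cohort with no DST response yields null comparisons", {
  cfg <- cohort_config(n_subjects = 150, n_variants = 60,
                       adjust_days_morning = 0, persistent_delay_evening = 0,
                       short_event_rate = 0, missing_night_rate = 0,
                       seed = 14)
  co <- simulate_cohort(cfg)
  rep <- run_full_analysis(co$events, co$genotypes, run_config())
  for (g in c("morning", "evening")) {
    expect_gt(rep$asleep_time[[g]]$p_value, 0.01)
    expect_gt(rep$sjl$comparisons[[g]]$p_value, 0.01)
  }
  d <- rep$profile_deltas
  expect_lt(max(abs(d$d_onset), na.rm = TRUE), 15)
})

test_that("re-running the full analysis is byte-identical", {
  cfg <- cohort_config(n_subjects = 60, n_variants = 60, seed = 15)
  co <- simulate_cohort(cfg)
  r1 <- run_full_analysis(co$events, co$genotypes, run_config())
  r2 <- run_full_analysis(co$events, co$genotypes, run_config())
  d1 <- tempfile()
  d2 <- tempfile()
  write_report(r1, d1)
  write_report(r2, d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)),
                     label = f)
})
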