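# Post-inhalation binning, exclusion rules, three-level averaging, and
# inhalation-behavior summaries.

# One session tibble.
mk_session <- function(pid, start, end, complete = TRUE) {
  tibble::tibble(patient_id = pid,
                 start = as.POSIXct(start, tz = TZ),
                 end = as.POSIXct(end, tz = TZ),
                 complete = complete, dose_ug = 2.5)
}

test_that("constant-rate walking with full wear fills every bin equally", {
  # 10 m per minute from 08:00 onward, worn throughout
  s <- mk_stream("P1", "2024-03-01", 420:1020, steps = 12, distance_m = 10,
                 hr = 80)
  sess <- mk_session("P1", "2024-03-01 08:00:00", "2024-03-01 08:06:00")
  al <- align_sessions(s, sess)
  expect_true(al$included)
  expect_false(al$partial_first_bin)
  expect_equal(unlist(al[paste0("bin_", 1:12)], use.names = FALSE),
               rep(150, 12))
})

test_that("a wear gap in the 3-hour tail excludes the session", {
  mins <- setdiff(420:1020, 486 + 170)   # unworn minute 170 after the end
  s <- mk_stream("P1", "2024-03-01", mins, steps = 12, distance_m = 10,
                 hr = 80)
  sess <- mk_session("P1", "2024-03-01 08:00:00", "2024-03-01 08:06:00")
  al <- align_sessions(s, sess)
  expect_false(al$included)
  expect_equal(al$reason, "wear_gap")

  # a session ending after stream coverage is excluded too
  sess_late <- mk_session("P1", "2024-03-01 17:30:00", "2024-03-01 17:36:00")
  al2 <- align_sessions(s, sess_late)
  expect_false(al2$included)
  expect_equal(al2$reason, "beyond_coverage")
})

test_that("the first bin tolerates partial wear unless strict mode is on", {
  mins <- setdiff(420:1020, 486 + 3)     # unworn minute 3 after the end
  s <- mk_stream("P1", "2024-03-01", mins, steps = 12, distance_m = 10,
                 hr = 80)
  sess <- mk_session("P1", "2024-03-01 08:00:00", "2024-03-01 08:06:00")
  al <- align_sessions(s, sess)
  expect_true(al$included)
  expect_true(al$partial_first_bin)
  # the partial first bin is a raw, unscaled sum over its 14 worn minutes
  expect_equal(al$bin_1, 140)
  expect_equal(al$bin_2, 150)

  strict <- analysis_config(strict_wear_exclusion = TRUE)
  al_s <- align_sessions(s, sess, strict)
  expect_false(al_s$included)
})

test_that("sessions ending mid-minute snap to the next whole minute", {
  s <- mk_stream("P1", "2024-03-01", 420:1020, steps = 12,
                 distance_m = 1:601, hr = 80)
  a <- align_sessions(s, mk_session("P1", "2024-03-01 08:00:00",
                                    "2024-03-01 08:05:30"))
  b <- align_sessions(s, mk_session("P1", "2024-03-01 08:00:30",
                                    "2024-03-01 08:06:00"))
  expect_equal(unlist(a[paste0("bin_", 1:12)]),
               unlist(b[paste0("bin_", 1:12)]))
})

test_that("overlapping sessions each contribute and match the brute-force oracle", {
  set.seed(41)
  steps <- rpois(601, 6)
  s <- mk_stream("P1", "2024-03-01", 420:1020, steps = steps,
                 distance_m = steps, hr = 80)
  sess <- rbind(
    mk_session("P1", "2024-03-01 08:00:00", "2024-03-01 08:05:24"),
    mk_session("P1", "2024-03-01 08:30:00", "2024-03-01 08:36:00")
  )
  al <- align_sessions(s, sess, measure = "steps")
  expect_true(all(al$included))
  for (i in 1:2) {
    oracle <- oracle_bin_sums(s, sess$end[i], measure = "steps")
    expect_identical(unname(unlist(al[i, paste0("bin_", 1:12)])), oracle$bins)
  }
})

test_that("shifting stream and session together leaves bin vectors unchanged", {
  set.seed(42)
  steps <- rpois(400, 6)
  s1 <- mk_stream("P1", "2024-03-01", 420:819, steps = steps,
                  distance_m = steps, hr = 80)
  s2 <- mk_stream("P1", "2024-03-01", 420:819 + 37, steps = steps,
                  distance_m = steps, hr = 80)
  a1 <- align_sessions(s1, mk_session("P1", "2024-03-01 07:10:00",
                                      "2024-03-01 07:15:00"),
                       measure = "steps")
  a2 <- align_sessions(s2, mk_session("P1", "2024-03-01 07:47:00",
                                      "2024-03-01 07:52:00"),
                       measure = "steps")
  expect_identical(unlist(a1[paste0("bin_", 1:12)]),
                   unlist(a2[paste0("bin_", 1:12)]))
})

test_that("three-level averaging: sessions within day, then across patient-days", {
  mk_aligned_row <- function(pid, date, bin1) {
    row <- tibble::tibble(patient_id = pid, date = as.Date(date),
                          start = at_min(date, 600), end = at_min(date, 606),
                          included = TRUE, reason = NA_character_,
                          partial_first_bin = FALSE)
    bins <- c(bin1, rep(10, 11))
    row[paste0("bin_", 1:12)] <- as.list(bins)
    row
  }
  # one patient-day with sessions at 100 and 200 -> patient-day bin 1 is 150
  al <- rbind(mk_aligned_row("A", "2024-03-01", 100),
              mk_aligned_row("A", "2024-03-01", 200))
  cv <- average_curves(al)
  expect_equal(cv$patient_day_curves$bin_1, 150)
  # add a second patient-day with bin 1 of 50 -> cohort bin 1 is 100
  al2 <- rbind(al, mk_aligned_row("B", "2024-03-02", 50))
  cv2 <- average_curves(al2)
  expect_equal(cv2$cohort_means[1], 100)
  expect_equal(cv2$n_patient_days, 2L)

  # zero included sessions is an error
  al_none <- al
  al_none$included <- FALSE
  expect_error(average_curves(al_none), "no included")
})

test_that("cohort curve equals the hand-coded three-level loop on a varied fixture", {
  set.seed(43)
  streams <- list()
  sess_all <- list()
  for (pid in c("A", "B", "C")) {
    days_minutes <- lapply(0:4, function(d) {
      worn <- 380:1430
      gap_starts <- sample(seq(400, 1200, by = 10), 2)
      for (g in gap_starts) worn <- setdiff(worn, g:(g + 29))
      d * 1440 + worn
    })
    mins <- unlist(days_minutes)
    steps <- rpois(length(mins), 5)
    streams[[pid]] <- mk_stream(pid, "2024-03-01", mins, steps = steps,
                                distance_m = steps, hr = 80)
    n_sess <- sample(2:4, 5, replace = TRUE)
    sess_all[[pid]] <- dplyr::bind_rows(lapply(0:4, function(d) {
      starts <- sort(sample(seq(480, 900, by = 40), n_sess[d + 1]))
      tibble::tibble(
        patient_id = pid,
        start = at_min("2024-03-01", d * 1440 + starts),
        end = at_min("2024-03-01", d * 1440 + starts) + 330,
        complete = TRUE, dose_ug = 2.5)
    }))
  }
  aligned <- align_cohort(streams, dplyr::bind_rows(sess_all),
                          measure = "steps")
  expect_gt(sum(aligned$included), 0)
  cv <- average_curves(aligned, "steps")
  oracle <- oracle_three_level(aligned)
  expect_equal(cv$cohort_means, oracle$cohort, tolerance = 1e-12)
})

test_that("inhalation behavior summaries match daily tallies", {
  tl <- mk_timeline("P1", "2024-03-01", baseline_days = 5,
                    observation_days = 10)
  # day 1: 4 complete + 1 incomplete -> 80% complete
  day1 <- lapply(1:5, function(i)
    mk_session("P1", at_min("2024-03-01", 400 + i * 100),
               at_min("2024-03-01", 405 + i * 100), complete = i <= 4))
  # days 2 and 3: 5 and 6 sessions
  day2 <- lapply(1:5, function(i)
    mk_session("P1", at_min("2024-03-02", 400 + i * 100),
               at_min("2024-03-02", 406 + i * 100)))
  day3 <- lapply(1:6, function(i)
    mk_session("P1", at_min("2024-03-03", 400 + i * 90),
               at_min("2024-03-03", 404 + i * 90)))
  sess <- dplyr::bind_rows(c(day1, day2, day3))
  b <- inhalation_behavior(sess, tl)
  pp <- b$per_patient
  # daily counts {5,5,6} on session days, 0 on the other 7 observation days
  expect_equal(pp$n_sessions, 16L)
  expect_equal(pp$n_days, 10L)
  expect_equal(pp$mean_daily_sessions, 1.6)
  expect_equal(pp$median_daily_duration_min, 5)      # daily means {5,6,4}
  expect_equal(pp$median_daily_pct_complete, 100)    # {80,100,100}

  # cohort medians over a 2-patient fixture equal brute-force values
  tl2 <- rbind(tl, mk_timeline("P2", "2024-03-01", baseline_days = 5,
                               observation_days = 10))
  sess2 <- rbind(sess, dplyr::bind_rows(lapply(1:3, function(i)
    mk_session("P2", at_min("2024-03-02", 400 + i * 100),
               at_min("2024-03-02", 410 + i * 100)))))
  b2 <- inhalation_behavior(sess2, tl2)
  med_dur <- b2$cohort$median[b2$cohort$statistic == "median_daily_duration_min"]
  expect_equal(med_dur, median(c(5, 10)))
  # a patient with zero sessions is reported absent, not zero
  tl3 <- rbind(tl2, mk_timeline("P3", "2024-03-01", baseline_days = 5,
                                observation_days = 10))
  b3 <- inhalation_behavior(sess2, tl3)
  expect_true(is.na(b3$per_patient$median_daily_sessions[
    b3$per_patient$patient_id == "P3"]))
  expect_equal(b3$cohort$n[1], 2L)
})
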