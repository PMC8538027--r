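# Period medians, change-from-baseline semantics, and analysis-set filters.

steps_only <- c(steps = "norm_steps")

test_that("baseline median uses non-missing pre-treatment days", {
  tl <- mk_timeline("P1", "2024-03-15")
  daily <- mk_daily("P1", as.Date("2024-03-10") + 0:2,
                    steps = c(3000, 4000, 5000))
  out <- summarize_baseline(daily, tl, measures = steps_only)
  expect_equal(out$value, 4000)
  expect_equal(out$n_days, 3L)

  # all pre-treatment days missing -> absent with n 0
  daily_m <- mk_daily("P1", as.Date("2024-03-10") + 0:2,
                      steps = NA_real_, missing = TRUE, wear_minutes = 50)
  out_m <- summarize_baseline(daily_m, tl, measures = steps_only)
  expect_true(is.na(out_m$value))
  expect_equal(out_m$n_days, 0L)
})

test_that("only the most recent 14 calendar days enter the baseline median", {
  tl <- mk_timeline("P1", "2024-03-20", baseline_days = 16)
  dates <- as.Date("2024-03-04") + 0:15      # 16 pre-treatment days
  vals <- seq(1000, 2500, by = 100)
  daily <- mk_daily("P1", dates, steps = vals)
  out <- summarize_baseline(daily, tl, measures = steps_only)
  # brute-force oracle: median over the last 14 calendar days only
  keep <- dates >= as.Date("2024-03-20") - 14
  expect_equal(sum(keep), 14L)
  expect_equal(out$value, median(vals[keep]))
  expect_equal(out$n_days, 14L)
  # treatment-start day itself never enters the baseline
  d2 <- rbind(daily, mk_daily("P1", as.Date("2024-03-20"), steps = 99999))
  expect_equal(summarize_baseline(d2, tl, measures = steps_only)$value,
               out$value)
})

test_that("end summary covers the last 14 days with even-count midpoint medians", {
  tl <- mk_timeline("P1", "2024-03-15", observation_days = 91)
  win_start <- tl$observation_end - 13
  daily <- mk_daily("P1", seq(win_start, tl$observation_end, by = "day"),
                    steps = 6000)
  out <- summarize_end(daily, tl, measures = steps_only)
  expect_equal(out$value, 6000)
  expect_equal(out$n_days, 14L)

  # only two non-missing days in the window: midpoint of 5000 and 7000
  daily2 <- mk_daily("P1", win_start + c(1, 3), steps = c(5000, 7000))
  out2 <- summarize_end(daily2, tl, measures = steps_only)
  expect_equal(out2$value, 6000)
  expect_equal(out2$n_days, 2L)

  # days the watch was never worn are simply not there
  daily3 <- rbind(daily2,
                  mk_daily("P1", win_start + c(5, 6), steps = NA_real_,
                           missing = TRUE, wear_minutes = 30))
  expect_equal(summarize_end(daily3, tl, measures = steps_only)$value, 6000)
})

test_that("median operator is permutation invariant and matches a sort oracle", {
  set.seed(31)
  tl <- mk_timeline("P1", "2024-03-15")
  for (i in 1:10) {
    n <- sample(1:14, 1)
    vals <- round(runif(n, 0, 10000))
    sorted <- sort(vals)
    oracle <- if (n %% 2 == 1) sorted[(n + 1) / 2] else
      (sorted[n / 2] + sorted[n / 2 + 1]) / 2
    for (perm in list(vals, rev(vals), sample(vals))) {
      daily <- mk_daily("P1", as.Date("2024-03-14") - seq_len(n) + 1,
                        steps = perm)
      expect_equal(summarize_baseline(daily, tl,
                                      measures = steps_only)$value, oracle)
    }
  }
})

test_that("change is per patient and the cohort change is the median of changes", {
  # single patient: 339 -> 366 gives a change of 27
  b <- tibble::tibble(patient_id = "P1", measure = "steps", value = 339,
                      n_days = 5L)
  e <- tibble::tibble(patient_id = "P1", measure = "steps", value = 366,
                      n_days = 14L)
  ch <- change_from_baseline(b, e)
  expect_equal(ch$change, 27)

  # cohort changes {-1, 0, 3} -> median 0
  b3 <- tibble::tibble(patient_id = c("A", "B", "C"), measure = "steps",
                       value = c(10, 10, 10), n_days = 3L)
  e3 <- tibble::tibble(patient_id = c("A", "B", "C"), measure = "steps",
                       value = c(9, 10, 13), n_days = 3L)
  expect_equal(cohort_change_summary(change_from_baseline(b3, e3))$median_change, 0)

  # change absent unless both period values are present
  b2 <- tibble::tibble(patient_id = c("A", "B"), measure = "steps",
                       value = c(10, NA), n_days = c(3L, 0L))
  e2 <- tibble::tibble(patient_id = c("A", "B"), measure = "steps",
                       value = c(12, 15), n_days = c(3L, 3L))
  ch2 <- change_from_baseline(b2, e2)
  expect_true(is.na(ch2$change[ch2$patient_id == "B"]))
  expect_equal(ch2$change[ch2$patient_id == "A"], 2)
})

test_that("median of changes differs from difference of medians", {
  # patients (baseline, end): (10,20), (30,25), (5,6)
  b <- tibble::tibble(patient_id = c("A", "B", "C"), measure = "m",
                      value = c(10, 30, 5), n_days = 3L)
  e <- tibble::tibble(patient_id = c("A", "B", "C"), measure = "m",
                      value = c(20, 25, 6), n_days = 3L)
  ch <- change_from_baseline(b, e)
  expect_equal(sort(ch$change), c(-5, 1, 10))
  med_of_changes <- cohort_change_summary(ch)$median_change
  diff_of_medians <- median(e$value) - median(b$value)
  expect_equal(med_of_changes, 1)
  expect_equal(diff_of_medians, 10)
  expect_false(med_of_changes == diff_of_medians)
})

test_that("identical baseline and end values give exactly zero changes", {
  set.seed(32)
  vals <- runif(8, 100, 1000)
  b <- tibble::tibble(patient_id = paste0("P", 1:8), measure = "steps",
                      value = vals, n_days = 3L)
  ch <- change_from_baseline(b, b)
  expect_identical(ch$change, rep(0, 8))
})

test_that("full-analysis-set filter excludes exactly the designed violations", {
  fx <- fas_fixture()
  m <- full_analysis_filter(fx$daily, fx$timeline, fx$visits, fx$safety)
  expect_equal(m$patient_id[m$in_full_set], "OK")
  expect_equal(m$exclusion_reasons[[which(m$patient_id == "OK")]], character(0))
  reason_of <- function(pid) m$exclusion_reasons[[which(m$patient_id == pid)]]
  expect_equal(reason_of("NODOSE"), "no_dose")
  expect_equal(reason_of("SCREEN"), "screening_failure")
  expect_equal(reason_of("BASE"), "baseline_activity")
  expect_equal(reason_of("END"), "end_activity")
  expect_equal(reason_of("OUTCOME"), "clinical_outcome")
  # full set implies safety set
  expect_true(all(!m$in_full_set | m$in_safety_set))
  expect_false(m$in_safety_set[m$patient_id == "NODOSE"])
  # one outcome at both visits suffices: OK has 6MWD only, no BNP
  expect_true(m$in_full_set[m$patient_id == "OK"])
})

test_that("adding a non-missing day never removes a patient from the full set", {
  fx <- fas_fixture()
  m0 <- full_analysis_filter(fx$daily, fx$timeline, fx$visits, fx$safety)
  expect_false(m0$in_full_set[m0$patient_id == "BASE"])
  # give BASE one more baseline day -> now meets the >=3 rule
  extra <- mk_daily("BASE", as.Date("2024-03-15") - 10, steps = 900,
                    wear_minutes = 540)
  m1 <- full_analysis_filter(rbind(fx$daily, extra), fx$timeline, fx$visits,
                             fx$safety)
  expect_true(m1$in_full_set[m1$patient_id == "BASE"])
  # everyone previously in stays in
  expect_true(all(m0$patient_id[m0$in_full_set] %in%
                    m1$patient_id[m1$in_full_set]))
})
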