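# Digital walk distance, heart-rate changes, chronotropic response,
# resting heart rate, and recovery curves.

mk_trace <- function(pre = rep(80, 5), in_hr = rep(100, 6),
                     post = c(90, 85, 82), steps = 500) {
  walk_test_trace("P1", "initial",
                  as.POSIXct("2024-03-01 10:00:00", tz = TZ),
                  pre_hr = pre, in_hr = in_hr, post_hr = post,
                  steps_in_test = steps)
}

test_that("digital walk distance is steps times stride, per-patient stride optional", {
  cfg <- analysis_config(stride_length_m = 0.8)
  tr <- mk_trace(steps = 500)
  expect_equal(digital_6mwd(tr, cfg), 400)
  expect_equal(digital_6mwd(mk_trace(steps = 0), cfg), 0)
  # a patient walking with 0.6 m stride scores 25% below the healthy 0.8 m model
  d_pat <- digital_6mwd(tr, cfg, stride_m = 0.6)
  expect_equal(d_pat / digital_6mwd(tr, cfg), 0.75)
  expect_true(is.na(digital_6mwd(mk_trace(steps = NA), cfg)))
})

test_that("digital walk distance is homogeneous in steps and stride", {
  set.seed(51)
  cfg <- analysis_config()
  for (i in 1:10) {
    steps <- sample(100:1000, 1)
    stride <- runif(1, 0.4, 1)
    k <- sample(2:5, 1)
    expect_equal(digital_6mwd(mk_trace(steps = k * steps), cfg, stride),
                 k * digital_6mwd(mk_trace(steps = steps), cfg, stride))
    expect_equal(digital_6mwd(mk_trace(steps = steps), cfg, k * stride),
                 k * digital_6mwd(mk_trace(steps = steps), cfg, stride))
  }
})

test_that("per-minute HR change is referenced to minute -1", {
  expect_equal(hr_during_test(mk_trace(pre = rep(80, 5),
                                       in_hr = rep(100, 6))),
               rep(20, 6))
  tr <- mk_trace(pre = rep(80, 5), in_hr = c(90, 95, 98, 100, 102, 103.9))
  expect_equal(hr_during_test(tr)[6], 23.9)
  expect_equal(hr_during_test(mk_trace(pre = rep(90, 5),
                                       in_hr = rep(90, 6))),
               rep(0, 6))
  tr_na <- mk_trace(pre = c(80, 80, 80, 80, NA))
  expect_true(all(is.na(hr_during_test(tr_na))))
})

test_that("chronotropic response is peak walking HR minus resting HR", {
  tr <- mk_trace(pre = rep(75, 5), in_hr = c(100, 110, 120, 115, 112, 108))
  expect_equal(chronotropic_response(tr), 45)
  expect_equal(chronotropic_response(mk_trace(pre = rep(100, 5),
                                              in_hr = rep(100, 6))), 0)
  # monotone increasing in-test HR peaks at minute 6
  tr_mono <- mk_trace(pre = rep(70, 5), in_hr = seq(90, 115, by = 5))
  expect_equal(chronotropic_response(tr_mono), 115 - 70)
  # no resting HR computable -> absent
  tr_short <- mk_trace(pre = rep(80, 2))
  expect_true(is.na(chronotropic_response(tr_short)))
})

test_that("peak dominance: response bounds every per-minute change plus offset", {
  set.seed(52)
  for (i in 1:10) {
    tr <- mk_trace(pre = runif(5, 70, 90), in_hr = runif(6, 95, 140))
    rest <- resting_hr(tr)
    ref <- tail(tr$pre_hr, 1)
    cr <- chronotropic_response(tr)
    ch <- hr_during_test(tr)
    expect_true(all(cr >= ch + (ref - rest) - 1e-12))
  }
})

test_that("resting HR over a stream averages zero-step worn minutes", {
  mins <- 480:489
  steps <- c(0, 0, 0, 0, 0, 3, 5, 0, 2, 0)
  hr <- c(70, 72, 74, 76, 78, 95, 99, 71, 90, 73)
  s <- mk_stream("P1", "2024-03-01", mins, steps = steps, hr = hr)
  # brute-force oracle over the 7 zero-step minutes
  expect_equal(resting_hr(s, as.Date("2024-03-01")),
               mean(hr[steps == 0]))

  s5 <- mk_stream("P1", "2024-03-01", 480:484, steps = 0,
                  hr = c(70, 72, 74, 76, 78))
  expect_equal(resting_hr(s5, as.Date("2024-03-01")), 74)

  s_act <- mk_stream("P1", "2024-03-01", 480:489, steps = 5, hr = 90)
  expect_true(is.na(resting_hr(s_act, as.Date("2024-03-01"))))

  # fewer qualifying minutes than the window -> absent
  s4 <- mk_stream("P1", "2024-03-01", 480:483, steps = 0, hr = 70)
  expect_true(is.na(resting_hr(s4, as.Date("2024-03-01"))))
})

test_that("recovery curve measures HR drop from test end with interpolation", {
  tr <- mk_trace(in_hr = c(100, 105, 110, 115, 118, 120),
                 post = c(110, 105, 100))
  rc <- recovery_curve(tr)
  expect_equal(unname(rc[c("t1", "t2", "t3")]), c(-10, -15, -20))
  # linear decay 120 -> 96 over 3 minutes: -12 at 1.5 min
  tr_lin <- mk_trace(in_hr = c(rep(100, 5), 120), post = c(112, 104, 96))
  rc_lin <- recovery_curve(tr_lin)
  expect_equal(unname(rc_lin["t1.5"]), -12)
  expect_equal(unname(rc_lin["t0.5"]), -4)
  # flat post-test HR recovers nothing
  tr_flat <- mk_trace(in_hr = rep(110, 6), post = rep(110, 5))
  expect_true(all(recovery_curve(tr_flat) == 0))
  # short post coverage truncates the curve
  tr_short <- mk_trace(post = c(110, 105))
  expect_equal(names(recovery_curve(tr_short)),
               c("t0.5", "t1", "t1.5", "t2"))
})

test_that("mirror-image post-test traces give negated recovery curves", {
  base <- c(rep(100, 5), 120)
  down <- mk_trace(in_hr = base, post = 120 - c(6, 12, 18))
  up <- mk_trace(in_hr = base, post = 120 + c(6, 12, 18))
  expect_equal(unname(recovery_curve(down)), -unname(recovery_curve(up)))
})

test_that("endpoint bundle collects all components coherently", {
  tr <- mk_trace(pre = rep(75, 5), in_hr = c(100, 110, 120, 115, 112, 108),
                 post = c(100, 92, 85), steps = 600)
  ep <- walk_test_endpoints(tr, analysis_config(stride_length_m = 0.7))
  expect_equal(ep$digital_6mwd_m, 420)
  expect_equal(ep$resting_hr_bpm, 75)
  expect_equal(ep$chronotropic_response_bpm, 45)
  expect_equal(length(ep$per_minute_hr_change), 6)
  expect_equal(unname(ep$recovery_curve["t3"]), 85 - 108)
})

test_that("walk-test traces round-trip through the CSV pair", {
  tr1 <- mk_trace()
  tr2 <- walk_test_trace("P2", "final",
                         as.POSIXct("2024-06-01 11:00:00", tz = TZ),
                         pre_hr = c(72, 74, 73, 75, 74),
                         in_hr = c(95, 100, 104, 107, 109, 110),
                         post_hr = c(100, 92, 86, 82),
                         steps_in_test = 430,
                         traditional_distance_m = 310)
  dir <- withr::local_tempdir()
  write_walk_traces(list(tr1, tr2), dir)
  back <- read_walk_traces(dir)
  expect_equal(back[["P2.final"]]$in_hr, tr2$in_hr)
  expect_equal(back[["P2.final"]]$steps_in_test, tr2$steps_in_test)
  expect_equal(back[["P1.initial"]]$pre_hr, tr1$pre_hr)
  expect_equal(back[["P1.initial"]]$test_start, tr1$test_start)
})
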