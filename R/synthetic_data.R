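# Seeded synthetic cohort generator with stored ground truth.
#
# Emulates a digitally monitored pulmonary-hypertension cohort: ~18
# patients observed for ~91 days after starting nebulized therapy, with a
# 4-14 day pre-treatment baseline; about 5 inhalation sessions/day of
# median 5.5 minutes, 90% complete; intermittent smartwatch wear (patient
# means spanning 4.8-11.5 h/day) inside the 6 AM-midnight window;
# circadian two-peak activity; a multiplicative post-inhalation activity
# boost decaying exponentially; a gradual (linearly ramped) treatment
# effect on daily distance; and heart rate driven by step rate around a
# patient-level resting value. Visit records and walk-test traces are tied
# to the latent activity so change-score correlations are nontrivial.
#
# All randomness flows from one seed: patient-level substreams are derived
# by drawing one sub-seed per patient up front, so regeneration under the
# same seed is byte-identical file by file.

#' Parameters of the synthetic cohort
#'
#' Defaults are anchored to the printed cohort summaries of the study this
#' pipeline targets: median 5.0 inhalation sessions/day of median 5.5
#' minutes, >75% complete (p = 0.9); patient mean wear between 4.8 and
#' 11.5 hours/day; median daily distance 5.2 km; resting heart rate around
#' 76 bpm; a +0.4 km treatment effect on daily distance ramped linearly
#' over the observation period; and a +20% post-inhalation activity boost
#' decaying over 60 minutes.
#'
#' @param n_patients Number of patients (default 18).
#' @param baseline_days_range Integer range of pre-treatment days per
#'   patient (default 4..14).
#' @param observation_days Length of the observation period (default 91).
#' @param sessions_per_day_mean Mean inhalation sessions per day (Poisson;
#'   default 5).
#' @param session_duration_median_min,session_duration_sdlog Lognormal
#'   session duration (median 5.5 min).
#' @param p_complete Probability a session is complete (default 0.9).
#' @param dose_ug Iloprost dose per session (default 2.5).
#' @param wear_hours_range Patient-level mean daily wear hours are drawn
#'   uniformly from this range (default 4.8..11.5).
#' @param wear_day_sd_hours Day-to-day SD of wear hours (default 1).
#' @param daily_distance_km_mean Cohort median of device-reported daily
#'   distance (km; default 5.2).
#' @param daily_distance_sdlog Patient-level lognormal spread (default
#'   0.5).
#' @param treatment_effect_km Added daily distance (km) at full ramp
#'   (default 0.4); each patient's realized effect is scaled by a
#'   N(1, response_sd) responder multiplier.
#' @param response_sd SD of the responder multiplier (default 0.6).
#' @param boost_amplitude Fractional post-inhalation activity increase at
#'   the moment a session ends (default 0.20).
#' @param boost_decay_min Exponential decay constant of the boost in
#'   minutes (default 60).
#' @param hr_rest_mean,hr_rest_sd Patient-level resting HR distribution
#'   (default 76, 8).
#' @param hr_activity_slope Heart-rate rise per step/min (default 0.3).
#' @param hr_noise_sd Per-minute HR noise SD (default 3).
#' @param device_stride_m Stride length the simulated watch uses to turn
#'   steps into distance (healthy calibration; default 0.78).
#' @param true_stride_mean,true_stride_sd Patients' actual stride length
#'   (default 0.62, 0.05) — shorter than the device calibration, so the
#'   digital walk distance overestimates the traditional one.
#' @param standups_per_day Mean standing-up events per day (default 24).
#' @param p_active Probability that a minute is a moving minute (default
#'   0.45); steps concentrate in moving minutes (Poisson with rate scaled
#'   by \code{1 / p_active}) so the expected minute rate is unchanged,
#'   while the remaining minutes are at rest with zero steps.
#' @param circadian Intraday activity profile: \code{"two_peak"} (morning
#'   and late-afternoon peaks) or \code{"flat"}.
#' @param six_mwd_intercept_m,six_mwd_per_km Linear map from latent daily
#'   distance to traditional 6-minute walk distance.
#' @param six_mwd_gain_per_km Traditional 6MWD change per km of realized
#'   treatment effect (default 65).
#' @param visit_noise_sd Measurement noise on visit 6MWD (default 15 m).
#' @param walk_steps_noise_sd Lognormal measurement error of the watch's
#'   in-test step count (default 0.07), decoupling the digital walk
#'   distance from the traditional one.
#' @param rng_seed Default seed used by \code{\link{generate_cohort}}.
#' @return A validated list of class \code{cohort_params}.
#' @export
cohort_params <- function(n_patients = 18,
                          baseline_days_range = c(4L, 14L),
                          observation_days = 91,
                          sessions_per_day_mean = 5.0,
                          session_duration_median_min = 5.5,
                          session_duration_sdlog = 0.25,
                          p_complete = 0.9,
                          dose_ug = 2.5,
                          wear_hours_range = c(4.8, 11.5),
                          wear_day_sd_hours = 1,
                          daily_distance_km_mean = 5.2,
                          daily_distance_sdlog = 0.5,
                          treatment_effect_km = 0.4,
                          response_sd = 0.6,
                          boost_amplitude = 0.20,
                          boost_decay_min = 60,
                          hr_rest_mean = 76,
                          hr_rest_sd = 8,
                          hr_activity_slope = 0.3,
                          hr_noise_sd = 3,
                          device_stride_m = 0.78,
                          true_stride_mean = 0.62,
                          true_stride_sd = 0.05,
                          standups_per_day = 24,
                          p_active = 0.45,
                          circadian = c("two_peak", "flat"),
                          six_mwd_intercept_m = 180,
                          six_mwd_per_km = 30,
                          six_mwd_gain_per_km = 65,
                          visit_noise_sd = 15,
                          walk_steps_noise_sd = 0.07,
                          rng_seed = 1L) {
  p <- as.list(environment())
  p$circadian <- match.arg(circadian)
  class(p) <- "cohort_params"
  validate_cohort_params(p)
}

#' @rdname cohort_params
#' @param x A \code{cohort_params} object.
#' @export
validate_cohort_params <- function(x) {
  stopifnot(
    x$n_patients >= 1, x$observation_days >= 15,
    length(x$baseline_days_range) == 2,
    x$baseline_days_range[1] >= 1,
    x$baseline_days_range[2] >= x$baseline_days_range[1],
    x$sessions_per_day_mean > 0, x$session_duration_median_min > 0,
    x$session_duration_median_min < 60,
    x$p_complete >= 0, x$p_complete <= 1,
    length(x$wear_hours_range) == 2,
    x$wear_hours_range[1] > 0, x$wear_hours_range[2] <= 18,
    x$wear_hours_range[2] >= x$wear_hours_range[1],
    x$daily_distance_km_mean > 0, x$boost_amplitude >= 0,
    x$p_active > 0, x$p_active <= 1,
    x$boost_decay_min > 0, x$device_stride_m > 0, x$true_stride_mean > 0
  )
  # the session schedule must fit inside the daily activity window
  if (x$sessions_per_day_mean * x$session_duration_median_min > 12 * 60) {
    .stopf("infeasible params: session schedule exceeds the daytime window")
  }
  x
}

# Two-peak circadian weight over the 1080 activity-window minutes,
# normalized to mean 1. Hour grid is 6..24.
.circadian_weights <- function(kind) {
  m <- seq(0, 1079)
  hour <- 6 + m / 60
  if (kind == "flat") return(rep(1, length(m)))
  w <- 0.35 + exp(-((hour - 10) / 2)^2) + 0.8 * exp(-((hour - 17) / 2.5)^2)
  w / mean(w)
}

.clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Random wear mask over the 1080-minute window: `blocks` contiguous worn
# blocks totalling `worn` minutes, at random non-overlapping positions.
.wear_mask <- function(worn, blocks = sample(2:3, 1)) {
  total <- 1080L
  worn <- .clip(as.integer(worn), 0L, total)
  if (worn == 0) return(logical(total))
  if (worn == total) return(rep(TRUE, total))
  blocks <- min(blocks, worn)
  cuts <- sort(sample.int(worn - 1, blocks - 1)) # worn minutes -> block sizes
  lens <- diff(c(0L, cuts, worn))
  gap_total <- total - worn
  gcuts <- sort(sample.int(gap_total + 1, blocks, replace = TRUE) - 1L)
  gaps <- diff(c(0L, gcuts, gap_total))          # blocks + 1 gaps
  mask <- logical(total)
  pos <- 0L
  for (b in seq_len(blocks)) {
    pos <- pos + gaps[b]
    mask[(pos + 1):(pos + lens[b])] <- TRUE
    pos <- pos + lens[b]
  }
  mask
}

# Simulate one patient; returns list(stream, sessions, timeline row,
# visits rows, traces, truth row).
.simulate_patient <- function(pid, sub_seed, p) {
  set.seed(sub_seed)
  enrollment <- as.Date("2024-03-01")
  baseline_days <- sample(seq(p$baseline_days_range[1],
                              p$baseline_days_range[2]), 1)
  treat_date <- enrollment + baseline_days
  obs_end <- treat_date + p$observation_days - 1
  dates <- seq(enrollment, obs_end, by = "day")
  n_days <- length(dates)

  base_km <- p$daily_distance_km_mean *
    exp(stats::rnorm(1, -p$daily_distance_sdlog^2 / 2, p$daily_distance_sdlog))
  response <- stats::rnorm(1, 1, p$response_sd)
  rest_hr <- .clip(stats::rnorm(1, p$hr_rest_mean, p$hr_rest_sd), 50, 110)
  true_stride <- .clip(stats::rnorm(1, p$true_stride_mean, p$true_stride_sd),
                       0.35, 0.95)
  wear_mean_h <- stats::runif(1, p$wear_hours_range[1], p$wear_hours_range[2])
  circ <- .circadian_weights(p$circadian)

  day0 <- as.POSIXct(paste(dates, "06:00:00"), tz = .TZ)
  first_session_start <- NA

  ts_list <- steps_list <- hr_list <- su_list <- vector("list", n_days)
  sess_list <- vector("list", n_days)
  km_by_day <- numeric(n_days)

  for (d in seq_len(n_days)) {
    is_obs <- dates[d] >= treat_date
    ramp <- if (is_obs) {
      as.integer(dates[d] - treat_date + 1) / p$observation_days
    } else 0
    km_d <- max(base_km + p$treatment_effect_km * response * ramp, 0.05)
    km_by_day[d] <- km_d
    steps_day <- km_d * 1000 / p$device_stride_m
    rate <- steps_day / 1080 * circ

    boost <- rep(0, 1080)
    if (is_obs) {
      n_s <- stats::rpois(1, p$sessions_per_day_mean)
      # sessions between 8:00 and 20:00, at least 20 min apart; the spacing
      # transform keeps the drawn count intact
      sep <- 20L
      span <- 720L
      n_s <- min(n_s, (span + sep) %/% (sep + 1L))
      if (n_s > 0) {
        avail <- span - (n_s - 1L) * sep
        start_min <- 120L + sort(sample.int(avail + 1L, n_s,
                                            replace = TRUE) - 1L) +
          (seq_len(n_s) - 1L) * sep
        dur <- .clip(stats::rlnorm(length(start_min),
                                   log(p$session_duration_median_min),
                                   p$session_duration_sdlog), 1, 25)
        start_t <- day0[d] + start_min * 60
        end_t <- start_t + round(dur * 60)
        sess_list[[d]] <- tibble(
          patient_id = pid, start = start_t, end = end_t,
          complete = stats::runif(length(start_min)) < p$p_complete,
          dose_ug = p$dose_ug
        )
        if (is.na(first_session_start)) first_session_start <- start_t[1]
        end_min_in_win <- (as.numeric(end_t) - as.numeric(day0[d])) / 60
        for (em in end_min_in_win) {
          t_rel <- seq(0, 1079) - em
          hit <- t_rel >= 0 & t_rel <= 180
          boost[hit] <- boost[hit] +
            p$boost_amplitude * exp(-t_rel[hit] / p$boost_decay_min)
        }
      }
    }

    wear_h <- .clip(stats::rnorm(1, wear_mean_h, p$wear_day_sd_hours), 1, 18)
    mask <- .wear_mask(round(wear_h * 60))
    widx <- which(mask)
    n_w <- length(widx)
    if (n_w == 0) next
    lambda <- rate[widx] * (1 + boost[widx])
    active <- stats::runif(n_w) < p$p_active
    steps <- integer(n_w)
    steps[active] <- stats::rpois(sum(active), lambda[active] / p$p_active)
    su <- stats::rpois(n_w, p$standups_per_day / 1080)
    hr <- .clip(rest_hr + p$hr_activity_slope * steps +
                  stats::rnorm(n_w, 0, p$hr_noise_sd), 40, 220)
    ts_list[[d]] <- day0[d] + (widx - 1) * 60
    steps_list[[d]] <- steps
    su_list[[d]] <- su
    hr_list[[d]] <- hr
  }

  steps_all <- unlist(steps_list)
  epochs <- tibble(
    timestamp = as.POSIXct(unlist(lapply(ts_list, as.numeric)), tz = .TZ,
                           origin = "1970-01-01"),
    steps = steps_all,
    distance_m = steps_all * p$device_stride_m,
    standup_events = unlist(su_list),
    heart_rate_bpm = unlist(hr_list)
  )
  stream <- sample_stream(pid, epochs)
  sessions <- bind_rows(sess_list)

  treatment_start <- if (!is.na(first_session_start)) first_session_start else
    as.POSIXct(paste(treat_date, "08:00:00"), tz = .TZ)
  timeline <- tibble(patient_id = pid, enrollment_date = enrollment,
                     treatment_start = treatment_start,
                     observation_end = obs_end)

  # visit records tied to the latent activity level
  six_i <- max(p$six_mwd_intercept_m + p$six_mwd_per_km * base_km +
                 stats::rnorm(1, 0, p$visit_noise_sd), 50)
  six_f <- max(six_i + p$six_mwd_gain_per_km * p$treatment_effect_km *
                 response + stats::rnorm(1, 0, p$visit_noise_sd), 50)
  borg_i <- .clip(round(stats::rnorm(1, 5, 1.5) * 2) / 2, 0, 10)
  borg_f <- .clip(borg_i - round(response + stats::rnorm(1, 0, 1)) / 2, 0, 10)
  use_bnp <- stats::runif(1) < 0.4
  bnp_i <- if (use_bnp) stats::rlnorm(1, log(180), 0.8) else NA_real_
  bnp_f <- if (use_bnp) bnp_i * exp(-0.15 * response +
                                      stats::rnorm(1, 0, 0.2)) else NA_real_
  nt_i <- if (!use_bnp) stats::rlnorm(1, log(1800), 1.0) else NA_real_
  nt_f <- if (!use_bnp) nt_i * exp(-0.15 * response +
                                     stats::rnorm(1, 0, 0.2)) else NA_real_
  eq_i <- .clip(stats::rnorm(1, 0.85, 0.12), -0.6, 1)
  eq_f <- .clip(eq_i + 0.02 + stats::rnorm(1, 0, 0.05), -0.6, 1)
  psqi_i <- .clip(round(stats::rnorm(1, 7, 3)), 0, 21)
  psqi_f <- .clip(psqi_i - stats::rbinom(1, 2, 0.4), 0, 21)
  who_f <- if (stats::runif(1) < 0.22) "II" else "III"
  visits <- tibble(
    patient_id = pid,
    visit = c("initial", "final"),
    six_mwd_m = c(six_i, six_f),
    borg = c(borg_i, borg_f),
    who_fc = c("III", who_f),
    bnp_ng_l = c(bnp_i, bnp_f),
    ntprobnp_ng_l = c(nt_i, nt_f),
    eq5d_index = c(eq_i, eq_f),
    psqi_global = c(psqi_i, psqi_f)
  )

  make_trace <- function(visit, six_mwd, at_date) {
    steps_test <- round(six_mwd / true_stride *
                          exp(stats::rnorm(1, 0, p$walk_steps_noise_sd)))
    peak <- .clip(rest_hr + 25 + six_mwd / 15, rest_hr + 10, 200)
    ramp_hr <- rest_hr + (peak - rest_hr) * (1 - exp(-(1:6) / 2))
    walk_test_trace(
      pid, visit,
      test_start = as.POSIXct(paste(at_date, "10:00:00"), tz = .TZ),
      pre_hr = .clip(rest_hr + stats::rnorm(5, 0, 2), 40, 220),
      in_hr = .clip(ramp_hr + stats::rnorm(6, 0, 2), 40, 220),
      post_hr = .clip(rest_hr + (peak - rest_hr) * exp(-(1:5) / 1.5) +
                        stats::rnorm(5, 0, 2), 40, 220),
      steps_in_test = steps_test,
      traditional_distance_m = six_mwd
    )
  }
  traces <- list(make_trace("initial", six_i, enrollment),
                 make_trace("final", six_f, obs_end))

  truth <- tibble(
    patient_id = pid, base_km = base_km, response = response,
    realized_effect_km = p$treatment_effect_km * response,
    true_stride_m = true_stride, rest_hr_bpm = rest_hr,
    wear_hours_mean = wear_mean_h, baseline_days = baseline_days
  )

  list(stream = stream, sessions = sessions, timeline = timeline,
       visits = visits, traces = traces, truth = truth,
       km_by_day = tibble(patient_id = pid, date = dates,
                          target_km = km_by_day))
}

#' Generate a synthetic cohort
#'
#' @param params A \code{\link{cohort_params}} object.
#' @param seed Integer seed; defaults to \code{params$rng_seed}. One
#'   sub-seed per patient is derived from it, so the output is reproduced
#'   exactly under the same seed.
#' @param dir Optional directory: when given, the cohort is also written
#'   out via \code{\link{write_cohort}}.
#' @return A list of class \code{actistep_cohort}: \code{streams} (named
#'   list of \code{\link{sample_stream}}s), \code{sessions},
#'   \code{timeline}, \code{visits} (tibbles), \code{traces} (list of
#'   \code{\link{walk_test_trace}}s), \code{ground_truth} (list with
#'   \code{patients} and \code{daily_target} tibbles plus the boost and
#'   stride parameters), and \code{params}.
#' @export
generate_cohort <- function(params = cohort_params(),
                            seed = params$rng_seed, dir = NULL) {
  validate_cohort_params(params)
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1, params$n_patients)
  pids <- sprintf("P%03d", seq_len(params$n_patients))
  sims <- purrr::map2(pids, sub_seeds,
                      function(pid, s) .simulate_patient(pid, s, params))
  streams <- setNames(lapply(sims, `[[`, "stream"), pids)
  cohort <- structure(
    list(
      streams = streams,
      sessions = bind_rows(lapply(sims, `[[`, "sessions")),
      timeline = bind_rows(lapply(sims, `[[`, "timeline")),
      visits = bind_rows(lapply(sims, `[[`, "visits")),
      traces = unlist(lapply(sims, `[[`, "traces"), recursive = FALSE),
      ground_truth = list(
        patients = bind_rows(lapply(sims, `[[`, "truth")),
        daily_target = bind_rows(lapply(sims, `[[`, "km_by_day")),
        boost_amplitude = params$boost_amplitude,
        boost_decay_min = params$boost_decay_min,
        device_stride_m = params$device_stride_m,
        treatment_effect_km = params$treatment_effect_km
      ),
      params = params
    ),
    class = "actistep_cohort"
  )
  names(cohort$traces) <- vapply(cohort$traces, function(tr)
    paste(tr$patient_id, tr$visit, sep = "."), character(1))
  if (!is.null(dir)) write_cohort(cohort, dir)
  cohort
}

#' @export
print.actistep_cohort <- function(x, ...) {
  cat(sprintf("<actistep_cohort> %d patients, %d sessions, %d visit rows\n",
              length(x$streams), nrow(x$sessions), nrow(x$visits)))
  invisible(x)
}

#' Write a cohort to a directory of plain-text files
#'
#' Layout: \code{streams/<patient>.csv}, \code{inhalations/<patient>.csv},
#' \code{timeline.csv}, \code{visits.csv}, \code{traces/} (see
#' \code{\link{write_walk_traces}}), \code{ground_truth.json}.
#'
#' @param cohort An \code{actistep_cohort}.
#' @param dir Output directory.
#' @return \code{dir}, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "streams"), showWarnings = FALSE,
             recursive = TRUE)
  dir.create(file.path(dir, "inhalations"), showWarnings = FALSE)
  for (pid in names(cohort$streams)) {
    write_sample_stream(cohort$streams[[pid]],
                        file.path(dir, "streams", paste0(pid, ".csv")))
    write_inhalation_log(
      cohort$sessions[cohort$sessions$patient_id == pid, , drop = FALSE],
      file.path(dir, "inhalations", paste0(pid, ".csv")))
  }
  write_timeline(cohort$timeline, file.path(dir, "timeline.csv"))
  write_visits(cohort$visits, file.path(dir, "visits.csv"))
  if (length(cohort$traces) > 0) {
    write_walk_traces(cohort$traces, file.path(dir, "traces"))
  }
  gt <- cohort$ground_truth
  jsonlite::write_json(
    list(patients = gt$patients,
         boost_amplitude = gt$boost_amplitude,
         boost_decay_min = gt$boost_decay_min,
         device_stride_m = gt$device_stride_m,
         treatment_effect_km = gt$treatment_effect_km),
    file.path(dir, "ground_truth.json"),
    dataframe = "columns", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cohort directory written by \code{\link{write_cohort}}
#'
#' @param dir Cohort directory.
#' @return An \code{actistep_cohort} (without ground truth unless
#'   \code{ground_truth.json} is present; without params).
#' @export
read_cohort <- function(dir) {
  timeline <- read_timeline(file.path(dir, "timeline.csv"))
  pids <- timeline$patient_id
  streams <- setNames(lapply(pids, function(pid) {
    read_sample_stream(file.path(dir, "streams", paste0(pid, ".csv")), pid)
  }), pids)
  sessions <- bind_rows(lapply(pids, function(pid) {
    read_inhalation_log(file.path(dir, "inhalations", paste0(pid, ".csv")),
                        pid)
  }))
  visits <- read_visits(file.path(dir, "visits.csv"))
  traces <- if (file.exists(file.path(dir, "traces", "traces.csv"))) {
    read_walk_traces(file.path(dir, "traces"))
  } else list()
  gt_path <- file.path(dir, "ground_truth.json")
  gt <- if (file.exists(gt_path)) {
    g <- jsonlite::read_json(gt_path, simplifyVector = TRUE)
    g$patients <- as_tibble(g$patients)
    g
  } else NULL
  structure(list(streams = streams, sessions = sessions,
                 timeline = timeline, visits = visits, traces = traces,
                 ground_truth = gt, params = NULL),
            class = "actistep_cohort")
}

#' Thin a cohort's wear time
#'
#' Randomly retains a fraction of each patient-day's worn minutes (epochs),
#' dropping the rest — emulating a watch worn less of the day. Ground truth
#' is untouched, so downstream estimates can still be compared against it.
#'
#' @param cohort An \code{actistep_cohort}.
#' @param target_fraction Fraction of worn minutes to keep, in (0, 1];
#'   1 is the identity.
#' @param seed Integer seed for the masking.
#' @return The cohort with thinned streams.
#' @export
degrade_wear <- function(cohort, target_fraction, seed = 1L) {
  if (!is.numeric(target_fraction) || target_fraction <= 0 ||
      target_fraction > 1) {
    .stopf("target_fraction must lie in (0, 1]")
  }
  if (target_fraction == 1) return(cohort)
  set.seed(seed)
  cohort$streams <- lapply(cohort$streams, function(stream) {
    e <- stream$epochs
    day <- .date_of(e$timestamp)
    keep <- unlist(lapply(split(seq_len(nrow(e)), day), function(idx) {
      n_keep <- floor(length(idx) * target_fraction)
      if (n_keep == 0) return(integer(0))
      sort(sample(idx, n_keep))
    }), use.names = FALSE)
    stream$epochs <- e[sort(keep), , drop = FALSE]
    stream
  })
  cohort
}
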