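# Fixture builders and independent brute-force oracles used across tests.

TZ <- "UTC"

# POSIXct at `date` + minutes after midnight
at_min <- function(date, minutes) {
  as.POSIXct(paste(date, "00:00:00"), tz = TZ) + minutes * 60
}

# Build a sample_stream from minute-of-day vectors (single or multiple days).
mk_stream <- function(pid, date, minutes, steps = 0L, distance_m = 0,
                      standups = 0L, hr = 80) {
  n <- length(minutes)
  sample_stream(pid, tibble::tibble(
    timestamp = at_min(date, minutes),
    steps = rep_len(steps, n),
    distance_m = rep_len(distance_m, n),
    standup_events = rep_len(standups, n),
    heart_rate_bpm = rep_len(hr, n)
  ))
}

# Minimal daily-activity rows for period-summary tests.
mk_daily <- function(pid, dates, steps = NA_real_, missing = FALSE,
                     wear_minutes = 540L, distance = NA_real_,
                     standups = NA_real_, resting_hr = NA_real_) {
  n <- length(dates)
  tibble::tibble(
    patient_id = pid,
    date = as.Date(dates),
    window_minutes = 1080L,
    wear_minutes = rep_len(as.integer(wear_minutes), n),
    wear_fraction = rep_len(wear_minutes, n) / 1080,
    raw_distance_m = 0, raw_steps = 0, raw_standups = 0,
    norm_distance_m = rep_len(distance, n),
    norm_steps = rep_len(steps, n),
    norm_standups = rep_len(standups, n),
    mean_hr_bpm = NA_real_,
    resting_hr_bpm = rep_len(resting_hr, n),
    missing = rep_len(missing, n)
  )
}

mk_timeline <- function(pid, treat_date, baseline_days = 14,
                        observation_days = 91) {
  treat_date <- as.Date(treat_date)
  tibble::tibble(
    patient_id = pid,
    enrollment_date = treat_date - baseline_days,
    treatment_start = as.POSIXct(paste(treat_date, "08:00:00"), tz = TZ),
    observation_end = treat_date + observation_days - 1
  )
}

mk_visit_row <- function(pid, visit, six_mwd = NA_real_, borg = NA_real_,
                         who = NA_character_, bnp = NA_real_,
                         nt = NA_real_, eq5d = NA_real_, psqi = NA_real_) {
  tibble::tibble(patient_id = pid, visit = visit, six_mwd_m = six_mwd,
                 borg = borg, who_fc = who, bnp_ng_l = bnp,
                 ntprobnp_ng_l = nt, eq5d_index = eq5d, psqi_global = psqi)
}

# 6-patient membership fixture: each patient violates exactly one
# full-analysis-set criterion; "OK" satisfies them all.
fas_fixture <- function() {
  treat <- as.Date("2024-03-15")
  tl <- dplyr::bind_rows(lapply(c("OK", "NODOSE", "SCREEN", "BASE", "END",
                                  "OUTCOME"), mk_timeline,
                                treat_date = treat, baseline_days = 14,
                                observation_days = 91))
  mk_period_days <- function(pid, n_base, n_end) {
    dplyr::bind_rows(
      mk_daily(pid, treat - seq_len(n_base), steps = 1000,
               wear_minutes = 540),
      mk_daily(pid, max(tl$observation_end) - seq_len(n_end) + 1,
               steps = 1200, wear_minutes = 540)
    )
  }
  daily <- dplyr::bind_rows(
    mk_period_days("OK", 5, 5),
    mk_period_days("NODOSE", 5, 5),
    mk_period_days("SCREEN", 5, 5),
    mk_period_days("BASE", 2, 5),      # < 3 baseline activity days
    mk_period_days("END", 5, 2),       # < 3 end-period activity days
    mk_period_days("OUTCOME", 5, 5)
  )
  visits <- dplyr::bind_rows(
    mk_visit_row("OK", "initial", six_mwd = 339),
    mk_visit_row("OK", "final", six_mwd = 366),
    mk_visit_row("NODOSE", "initial", six_mwd = 300),
    mk_visit_row("NODOSE", "final", six_mwd = 310),
    mk_visit_row("SCREEN", "initial", six_mwd = 300),
    mk_visit_row("SCREEN", "final", six_mwd = 310),
    mk_visit_row("BASE", "initial", six_mwd = 300),
    mk_visit_row("BASE", "final", six_mwd = 310),
    mk_visit_row("END", "initial", six_mwd = 300),
    mk_visit_row("END", "final", six_mwd = 310),
    # walk distance at one visit only, nothing else at both
    mk_visit_row("OUTCOME", "initial", six_mwd = 300, bnp = 100),
    mk_visit_row("OUTCOME", "final", borg = 4)
  )
  safety <- tibble::tibble(
    patient_id = c("OK", "NODOSE", "SCREEN", "BASE", "END", "OUTCOME"),
    received_dose = c(TRUE, FALSE, TRUE, TRUE, TRUE, TRUE),
    consent_withdrawn = FALSE,
    screening_failure = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE)
  )
  list(daily = daily, timeline = tl, visits = visits, safety = safety)
}

# --- independent oracles -----------------------------------------------------

# Brute-force post-inhalation bin sums: enumerate every minute explicitly.
# Returns list(bins, worn_ok_tail, worn_ok_all, any_unworn_bin1).
oracle_bin_sums <- function(stream, session_end, n_bins = 12,
                            bin_minutes = 15, measure = "steps") {
  e <- stream$epochs
  mins <- floor(as.numeric(e$timestamp) / 60)
  end_min <- ceiling(as.numeric(session_end) / 60)
  bins <- numeric(n_bins)
  unworn_in_bin <- logical(n_bins)
  for (b in seq_len(n_bins)) {
    for (j in seq_len(bin_minutes)) {
      minute <- end_min + (b - 1) * bin_minutes + (j - 1)
      row <- which(mins == minute)
      worn <- length(row) == 1 && !is.na(e$heart_rate_bpm[row])
      if (worn) {
        bins[b] <- bins[b] +
          if (measure == "steps") e$steps[row] else e$distance_m[row]
      } else {
        unworn_in_bin[b] <- TRUE
      }
    }
  }
  list(bins = bins,
       worn_ok_tail = !any(unworn_in_bin[-1]),
       worn_ok_all = !any(unworn_in_bin),
       any_unworn_bin1 = unworn_in_bin[1])
}

# Hand-coded three-level average over an aligned-session table.
oracle_three_level <- function(aligned, n_bins = 12) {
  inc <- aligned[aligned$included, , drop = FALSE]
  keys <- unique(paste(inc$patient_id, inc$date))
  pd_mat <- matrix(NA_real_, nrow = length(keys), ncol = n_bins)
  for (i in seq_along(keys)) {
    rows <- which(paste(inc$patient_id, inc$date) == keys[i])
    for (b in seq_len(n_bins)) {
      vals <- inc[[paste0("bin_", b)]][rows]
      pd_mat[i, b] <- sum(vals) / length(vals)
    }
  }
  cohort <- numeric(n_bins)
  for (b in seq_len(n_bins)) cohort[b] <- sum(pd_mat[, b]) / nrow(pd_mat)
  list(patient_day = pd_mat, cohort = cohort)
}

# Textbook Pearson correlation.
oracle_pearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  num / den
}

# Normal-equation least squares: intercept first.
oracle_ols <- function(X, y) {
  X1 <- cbind(1, as.matrix(X))
  beta <- solve(t(X1) %*% X1, t(X1) %*% y)
  fitted <- X1 %*% beta
  r2 <- 1 - sum((y - fitted)^2) / sum((y - mean(y))^2)
  list(beta = drop(beta), r_squared = r2)
}
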