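# Baseline / end-of-observation summaries, change from baseline, and
# analysis-set membership.
#
# Baseline is anchored on calendar days strictly before the date of the
# first inhalation (the treatment-start day itself belongs to the
# observation period) and uses at most the most recent `baseline_max_days`
# calendar days. The end period is the last `end_window_days` calendar days
# of observation. Period values are per-patient medians of the non-missing
# daily assessments; the cohort change is the median of per-patient changes,
# which is not in general the difference of the period medians.

# Default daily measures entering period summaries.
.DAILY_MEASURES <- c(
  distance = "norm_distance_m",
  steps = "norm_steps",
  standups = "norm_standups",
  resting_hr = "resting_hr_bpm"
)

#' Baseline and end-of-observation windows
#'
#' \code{baseline_window} covers the \code{baseline_max_days} calendar days
#' ending the day before the first inhalation; \code{end_window} covers the
#' last \code{end_window_days} calendar days of observation (inclusive of
#' \code{observation_end}).
#'
#' @param timeline Timeline tibble (see \code{\link{read_timeline}}).
#' @param config An \code{\link{analysis_config}}.
#' @return Tibble with columns \code{patient_id, window_start, window_end}.
#' @export
baseline_window <- function(timeline, config = analysis_config()) {
  tsd <- .date_of(timeline$treatment_start)
  tibble(
    patient_id = timeline$patient_id,
    window_start = tsd - config$baseline_max_days,
    window_end = tsd - 1
  )
}

#' @rdname baseline_window
#' @export
end_window <- function(timeline, config = analysis_config()) {
  tibble(
    patient_id = timeline$patient_id,
    window_start = timeline$observation_end - (config$end_window_days - 1),
    window_end = timeline$observation_end
  )
}

#' Restrict daily-activity rows to per-patient windows
#'
#' @param daily Daily-activity tibble (see \code{\link{aggregate_daily}}).
#' @param windows Window tibble from \code{\link{baseline_window}} or
#'   \code{\link{end_window}}.
#' @return The subset of \code{daily} with dates inside each patient's
#'   window.
#' @export
filter_to_windows <- function(daily, windows) {
  daily |>
    dplyr::inner_join(windows, by = "patient_id") |>
    filter(.data$date >= .data$window_start,
           .data$date <= .data$window_end) |>
    select(-"window_start", -"window_end")
}

# Long-format per-measure medians over one set of windows.
.summarize_windows <- function(daily, windows, measures) {
  sub <- filter_to_windows(daily, windows)
  sub <- sub[!sub$missing, , drop = FALSE]
  rows <- purrr::map_dfr(names(measures), function(m) {
    col <- measures[[m]]
    v <- sub[[col]]
    ok <- !is.na(v)
    sub[ok, ] |>
      group_by(patient_id = .data$patient_id) |>
      summarise(value = stats::median(.data[[col]]), n_days = dplyr::n(),
                .groups = "drop") |>
      mutate(measure = m)
  })
  # patients with zero eligible days get an explicit absent row
  all_pat <- unique(windows$patient_id)
  tidyr::expand_grid(patient_id = all_pat, measure = names(measures)) |>
    left_join(rows, by = c("patient_id", "measure")) |>
    mutate(n_days = ifelse(is.na(.data$n_days), 0L, as.integer(.data$n_days))) |>
    select("patient_id", "measure", "value", "n_days")
}

#' Per-patient baseline medians of daily activity measures
#'
#' Uses non-missing days strictly before the first inhalation's date,
#' restricted to the most recent \code{baseline_max_days} calendar days.
#' Medians use the midpoint convention for even counts. Patients with zero
#' eligible days get an absent value with \code{n_days = 0}.
#'
#' @param daily Daily-activity tibble.
#' @param timeline Timeline tibble.
#' @param config An \code{\link{analysis_config}}.
#' @param measures Named character vector mapping measure names to columns
#'   of \code{daily}.
#' @return Long tibble: \code{patient_id, measure, value, n_days}.
#' @export
summarize_baseline <- function(daily, timeline, config = analysis_config(),
                               measures = .DAILY_MEASURES) {
  .summarize_windows(daily, baseline_window(timeline, config), measures)
}

#' Per-patient end-of-observation medians of daily activity measures
#'
#' As \code{\link{summarize_baseline}}, over the last
#' \code{end_window_days} calendar days of the observation period.
#'
#' @inheritParams summarize_baseline
#' @return Long tibble: \code{patient_id, measure, value, n_days}.
#' @export
summarize_end <- function(daily, timeline, config = analysis_config(),
                          measures = .DAILY_MEASURES) {
  .summarize_windows(daily, end_window(timeline, config), measures)
}

#' Change from baseline per patient and measure
#'
#' Joins baseline and end summaries; the change is \code{end - baseline},
#' present only when both period values are present.
#'
#' @param baseline,end Long summary tibbles from
#'   \code{\link{summarize_baseline}} / \code{\link{summarize_end}}.
#' @return Tibble: \code{patient_id, measure, baseline_value,
#'   baseline_n_days, end_value, end_n_days, change}.
#' @export
change_from_baseline <- function(baseline, end) {
  baseline |>
    rename(baseline_value = "value", baseline_n_days = "n_days") |>
    dplyr::full_join(
      rename(end, end_value = "value", end_n_days = "n_days"),
      by = c("patient_id", "measure")
    ) |>
    mutate(change = .data$end_value - .data$baseline_value)
}

#' Cohort-level change summary
#'
#' Median of the per-patient changes with type-7 interquartile range. The
#' median of changes is a robust center estimate and is not in general
#' equal to the difference of the two period medians.
#'
#' @param changes Tibble from \code{\link{change_from_baseline}}.
#' @return Tibble: \code{measure, n, median_change, q1, q3}.
#' @export
cohort_change_summary <- function(changes) {
  changes |>
    filter(!is.na(.data$change)) |>
    group_by(measure = .data$measure) |>
    summarise(
      n = dplyr::n(),
      median_change = stats::median(.data$change),
      q1 = stats::quantile(.data$change, 0.25, names = FALSE, type = 7),
      q3 = stats::quantile(.data$change, 0.75, names = FALSE, type = 7),
      .groups = "drop"
    )
}

#' Analysis-set membership
#'
#' The safety analysis set holds every patient who received at least one
#' dose and did not fully withdraw consent. The full analysis set further
#' requires: not a screening failure; at least
#' \code{fas_min_baseline_days} non-missing activity days in the baseline
#' window; at least \code{fas_min_end_days} non-missing days in the last
#' \code{end_window_days} days of observation; and at least one clinical
#' outcome measure (6-minute walk distance, BNP or NT-proBNP, or WHO
#' functional class) available at both the initial and final visit.
#'
#' @param daily Daily-activity tibble for the cohort.
#' @param timeline Timeline tibble.
#' @param visits Visit-record tibble.
#' @param safety Tibble with columns \code{patient_id, received_dose,
#'   consent_withdrawn, screening_failure} (logical). If \code{NULL}, all
#'   patients are assumed dosed, consenting, and correctly enrolled.
#' @param config An \code{\link{analysis_config}}.
#' @return Tibble: \code{patient_id, in_safety_set, in_full_set,
#'   exclusion_reasons} (list column of tags drawn from \code{"no_dose"},
#'   \code{"consent_withdrawn"}, \code{"screening_failure"},
#'   \code{"baseline_activity"}, \code{"end_activity"},
#'   \code{"clinical_outcome"}).
#' @export
full_analysis_filter <- function(daily, timeline, visits, safety = NULL,
                                 config = analysis_config()) {
  pids <- timeline$patient_id
  if (is.null(safety)) {
    safety <- tibble(patient_id = pids, received_dose = TRUE,
                     consent_withdrawn = FALSE, screening_failure = FALSE)
  }
  n_base <- filter_to_windows(daily, baseline_window(timeline, config)) |>
    group_by(patient_id = .data$patient_id) |>
    summarise(n = sum(!.data$missing), .groups = "drop")
  n_end <- filter_to_windows(daily, end_window(timeline, config)) |>
    group_by(patient_id = .data$patient_id) |>
    summarise(n = sum(!.data$missing), .groups = "drop")

  outcome_ok <- vapply(pids, function(pid) {
    vi <- visits[visits$patient_id == pid & visits$visit == "initial", ]
    vf <- visits[visits$patient_id == pid & visits$visit == "final", ]
    if (nrow(vi) != 1 || nrow(vf) != 1) return(FALSE)
    both <- function(col) !is.na(vi[[col]]) && !is.na(vf[[col]])
    both("six_mwd_m") || both("who_fc") || both("bnp_ng_l") ||
      both("ntprobnp_ng_l")
  }, logical(1))

  purrr::map_dfr(seq_along(pids), function(i) {
    pid <- pids[i]
    s <- safety[safety$patient_id == pid, ]
    reasons <- character(0)
    if (nrow(s) != 1 || !isTRUE(s$received_dose)) {
      reasons <- c(reasons, "no_dose")
    }
    if (nrow(s) == 1 && isTRUE(s$consent_withdrawn)) {
      reasons <- c(reasons, "consent_withdrawn")
    }
    in_safety <- length(reasons) == 0
    if (nrow(s) == 1 && isTRUE(s$screening_failure)) {
      reasons <- c(reasons, "screening_failure")
    }
    nb <- n_base$n[match(pid, n_base$patient_id)]
    ne <- n_end$n[match(pid, n_end$patient_id)]
    if (is.na(nb) || nb < config$fas_min_baseline_days) {
      reasons <- c(reasons, "baseline_activity")
    }
    if (is.na(ne) || ne < config$fas_min_end_days) {
      reasons <- c(reasons, "end_activity")
    }
    if (!outcome_ok[i]) reasons <- c(reasons, "clinical_outcome")
    tibble(
      patient_id = pid,
      in_safety_set = in_safety,
      in_full_set = in_safety && length(reasons) == 0,
      exclusion_reasons = list(reasons)
    )
  })
}
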