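# Wear-time detection within the daily activity window and wear-fraction
# normalization of daily activity totals.
#
# A minute counts as "worn" iff an epoch exists for it AND the epoch carries
# a heart-rate sample: the optical heart-rate sensor requires skin contact,
# whereas the step counter can register off-wrist motion. Daily totals are
# summed over worn minutes inside the activity window (6 AM to midnight by
# default) and scaled up by 1 / wear_fraction — the assumed-18-hours
# normalization. Days with wear below `min_wear_fraction` are missing.

# Worn-minute predicate on an epoch tibble (within-window filter separate).
.worn <- function(epochs) !is.na(epochs$heart_rate_bpm)

.in_window <- function(timestamps, config) {
  hour <- .minute_of_day(timestamps) / 60
  hour >= config$activity_window_start_hour &
    hour < config$activity_window_end_hour
}

#' Count worn minutes on one date
#'
#' A minute is worn iff its epoch exists and carries a heart-rate sample,
#' and it falls inside the daily activity window. Dates outside the stream's
#' coverage yield 0, not an error.
#'
#' @param stream A \code{\link{sample_stream}}.
#' @param date A \code{Date}.
#' @param config An \code{\link{analysis_config}}.
#' @return Integer count of worn minutes in \code{[0, window_minutes]}.
#' @export
detect_wear_minutes <- function(stream, date, config = analysis_config()) {
  e <- stream$epochs
  keep <- .date_of(e$timestamp) == as.Date(date) &
    .in_window(e$timestamp, config) & .worn(e)
  sum(keep)
}

#' Aggregate one patient-day of activity
#'
#' Sums steps, distance and standing-up events over worn minutes within the
#' activity window, computes the wear fraction, and normalizes the totals to
#' the full window by dividing by the wear fraction. If the wear fraction is
#' below \code{config$min_wear_fraction} the day is flagged missing and all
#' normalized values are absent. Heart rate is averaged over worn minutes —
#' never scaled, since it is an intensity, not a count. A daily resting
#' heart rate (mean over zero-step worn minutes, reported only when at least
#' \code{config$resting_hr_window_min} such minutes exist) is included.
#'
#' @param stream A \code{\link{sample_stream}}.
#' @param date A \code{Date}.
#' @param config An \code{\link{analysis_config}}.
#' @return One-row tibble with the daily-activity fields.
#' @export
aggregate_day <- function(stream, date, config = analysis_config()) {
  aggregate_daily(stream, as.Date(date), config)
}

#' Aggregate a patient's activity over a set of dates
#'
#' Vectorized form of \code{\link{aggregate_day}}: one output row per
#' requested date (dates with no epochs yield wear 0 and a missing day).
#'
#' @param stream A \code{\link{sample_stream}}.
#' @param dates Vector of \code{Date}s.
#' @param config An \code{\link{analysis_config}}.
#' @return Tibble with columns \code{patient_id, date, window_minutes,
#'   wear_minutes, wear_fraction, raw_distance_m, raw_steps, raw_standups,
#'   norm_distance_m, norm_steps, norm_standups, mean_hr_bpm,
#'   resting_hr_bpm, missing}.
#' @export
aggregate_daily <- function(stream, dates, config = analysis_config()) {
  dates <- sort(unique(as.Date(dates)))
  wmin <- window_minutes(config)
  e <- stream$epochs
  keep <- .in_window(e$timestamp, config) & .worn(e)
  e <- e[keep, , drop = FALSE]
  e$date <- .date_of(e$timestamp)
  e <- e[e$date %in% dates, , drop = FALSE]

  agg <- e |>
    group_by(date = .data$date) |>
    summarise(
      wear_minutes = dplyr::n(),
      raw_distance_m = sum(.data$distance_m),
      raw_steps = sum(.data$steps),
      raw_standups = sum(.data$standup_events),
      mean_hr_bpm = mean(.data$heart_rate_bpm),
      n_rest = sum(.data$steps == 0),
      rest_hr_sum = sum(.data$heart_rate_bpm[.data$steps == 0]),
      .groups = "drop"
    )

  out <- tibble(patient_id = stream$patient_id, date = dates) |>
    left_join(agg, by = "date") |>
    mutate(
      window_minutes = wmin,
      wear_minutes = ifelse(is.na(.data$wear_minutes), 0L,
                            as.integer(.data$wear_minutes)),
      raw_distance_m = ifelse(is.na(.data$raw_distance_m), 0,
                              .data$raw_distance_m),
      raw_steps = ifelse(is.na(.data$raw_steps), 0, .data$raw_steps),
      raw_standups = ifelse(is.na(.data$raw_standups), 0, .data$raw_standups),
      wear_fraction = .data$wear_minutes / wmin,
      missing = .data$wear_fraction < config$min_wear_fraction,
      norm_distance_m = ifelse(.data$missing, NA_real_,
                               .data$raw_distance_m / .data$wear_fraction),
      norm_steps = ifelse(.data$missing, NA_real_,
                          .data$raw_steps / .data$wear_fraction),
      norm_standups = ifelse(.data$missing, NA_real_,
                             .data$raw_standups / .data$wear_fraction),
      resting_hr_bpm = ifelse(
        !is.na(.data$n_rest) & .data$n_rest >= config$resting_hr_window_min,
        .data$rest_hr_sum / .data$n_rest, NA_real_)
    ) |>
    select("patient_id", "date", "window_minutes", "wear_minutes",
           "wear_fraction", "raw_distance_m", "raw_steps", "raw_standups",
           "norm_distance_m", "norm_steps", "norm_standups", "mean_hr_bpm",
           "resting_hr_bpm", "missing")
  out
}

#' Aggregate daily activity for a whole cohort
#'
#' Runs \code{\link{aggregate_daily}} for every patient over their study
#' span (enrollment date through observation end).
#'
#' @param streams Named list of \code{\link{sample_stream}}s (names =
#'   patient ids).
#' @param timeline Timeline tibble (see \code{\link{read_timeline}}).
#' @param config An \code{\link{analysis_config}}.
#' @return Tibble of patient-day rows (see \code{\link{aggregate_daily}}).
#' @export
cohort_daily <- function(streams, timeline, config = analysis_config()) {
  purrr::map_dfr(timeline$patient_id, function(pid) {
    row <- timeline[timeline$patient_id == pid, ]
    if (is.null(streams[[pid]])) return(tibble())
    dates <- seq(row$enrollment_date, row$observation_end, by = "day")
    aggregate_daily(streams[[pid]], dates, config)
  })
}

#' Tabulate smartwatch use over a 14-day period
#'
#' Reproduces the standard cohort-description categories: number of days the
#' watch was worn (a day is worn iff it is not missing) in the bands
#' \code{<7}, \code{>=7}, \code{>=10} and \code{14} days, and average daily
#' hours worn (over worn days) in the bands \code{<6}, \code{>=6},
#' \code{>=10}, \code{>=14} and \code{18} hours. Bands overlap by design
#' (\code{>=7} includes \code{>=10}); boundaries are inclusive on the
#' \code{>=} side.
#'
#' @param daily Daily-activity tibble already restricted to one 14-day
#'   period per patient (see \code{\link{baseline_window}} /
#'   \code{\link{end_window}} and \code{\link{filter_to_windows}}).
#' @return Tibble with columns \code{group} ("days_worn" or "avg_hours"),
#'   \code{category}, \code{n_patients}. An empty cohort yields all-zero
#'   counts.
#' @export
wear_use_table <- function(daily) {
  per_patient <- daily |>
    group_by(patient_id = .data$patient_id) |>
    summarise(
      days_worn = sum(!.data$missing),
      avg_hours = if (any(!.data$missing)) {
        mean(.data$wear_minutes[!.data$missing]) / 60
      } else NA_real_,
      .groups = "drop"
    )
  d <- per_patient$days_worn
  h <- per_patient$avg_hours
  tibble(
    group = c(rep("days_worn", 4), rep("avg_hours", 5)),
    category = c("<7 days", ">=7 days", ">=10 days", "14 days",
                 "<6 hours", ">=6 hours", ">=10 hours", ">=14 hours",
                 "18 hours"),
    n_patients = c(
      sum(d < 7), sum(d >= 7), sum(d >= 10), sum(d == 14),
      sum(h < 6, na.rm = TRUE), sum(h >= 6, na.rm = TRUE),
      sum(h >= 10, na.rm = TRUE), sum(h >= 14, na.rm = TRUE),
      sum(h >= 18, na.rm = TRUE)
    )
  )
}
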