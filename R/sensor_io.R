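# Ingestion and validation of sensor streams, inhalation logs, visit
# records, study timelines and the analysis configuration.

# analysis_config ------------------------------------------------------------

#' Analysis configuration
#'
#' Bundles the constants that parameterize the pipeline. Defaults encode the
#' study conventions: an 18-hour daily activity window (6 AM to midnight),
#' days with less than 10% wear treated as missing, baseline and end windows
#' of 14 calendar days, at least 3 non-missing activity days per period for
#' full-analysis-set membership, and 12 x 15-minute post-inhalation bins.
#'
#' @param activity_window_start_hour First hour (inclusive) of the daily
#'   activity window; default 6 (6 AM).
#' @param activity_window_end_hour End hour (exclusive) of the window;
#'   default 24 (midnight).
#' @param min_wear_fraction Days with wear fraction below this are flagged
#'   missing; default 0.10.
#' @param baseline_max_days Maximum number of calendar days before the first
#'   inhalation that enter the baseline median; default 14.
#' @param end_window_days Length of the end-of-observation window in calendar
#'   days; default 14.
#' @param fas_min_baseline_days,fas_min_end_days Minimum non-missing activity
#'   days in each period for full-analysis-set membership; default 3.
#' @param n_bins,bin_minutes Number and width (minutes) of post-inhalation
#'   bins; defaults 12 and 15 (a 3-hour horizon).
#' @param stride_length_m Constant stride length (meters) used by the digital
#'   6-minute-walk-distance model unless a per-patient stride is supplied;
#'   default 0.78, typical of healthy-adult calibration.
#' @param resting_hr_window_min Minimum number of qualifying zero-step worn
#'   minutes needed to report a resting heart rate; default 5.
#' @param strict_wear_exclusion If \code{TRUE}, a post-inhalation window is
#'   excluded when any of its minutes (including the first bin) is unworn;
#'   the default (\code{FALSE}) tolerates partial wear in the first bin only.
#' @param rng_seed Optional integer seed recorded with the configuration.
#'
#' @return An object of class \code{analysis_config} (a validated list).
#' @export
analysis_config <- function(activity_window_start_hour = 6,
                            activity_window_end_hour = 24,
                            min_wear_fraction = 0.10,
                            baseline_max_days = 14,
                            end_window_days = 14,
                            fas_min_baseline_days = 3,
                            fas_min_end_days = 3,
                            n_bins = 12,
                            bin_minutes = 15,
                            stride_length_m = 0.78,
                            resting_hr_window_min = 5,
                            strict_wear_exclusion = FALSE,
                            rng_seed = NULL) {
  cfg <- list(
    activity_window_start_hour = activity_window_start_hour,
    activity_window_end_hour = activity_window_end_hour,
    min_wear_fraction = min_wear_fraction,
    baseline_max_days = as.integer(baseline_max_days),
    end_window_days = as.integer(end_window_days),
    fas_min_baseline_days = as.integer(fas_min_baseline_days),
    fas_min_end_days = as.integer(fas_min_end_days),
    n_bins = as.integer(n_bins),
    bin_minutes = as.integer(bin_minutes),
    stride_length_m = stride_length_m,
    resting_hr_window_min = as.integer(resting_hr_window_min),
    strict_wear_exclusion = isTRUE(strict_wear_exclusion),
    rng_seed = rng_seed
  )
  class(cfg) <- "analysis_config"
  validate_analysis_config(cfg)
}

#' @rdname analysis_config
#' @param x An \code{analysis_config}.
#' @export
validate_analysis_config <- function(x) {
  num <- x[setdiff(names(x), c("rng_seed", "strict_wear_exclusion"))]
  if (!all(vapply(num, function(v) is.numeric(v) && length(v) == 1 && v > 0,
                  logical(1)))) {
    .stopf("all analysis_config numeric fields must be positive scalars")
  }
  if (x$activity_window_end_hour <= x$activity_window_start_hour) {
    .stopf("activity window end hour must exceed start hour")
  }
  if (x$activity_window_end_hour > 24) {
    .stopf("activity window must lie within a single calendar day")
  }
  if (x$min_wear_fraction >= 1) .stopf("min_wear_fraction must be < 1")
  x
}

#' Read an analysis configuration from a JSON or YAML key-value file
#'
#' Unknown keys are rejected; missing keys take their defaults.
#'
#' @param path Path to a \code{.json}, \code{.yaml} or \code{.yml} file.
#' @return An \code{analysis_config}.
#' @export
read_analysis_config <- function(path) {
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- names(formals(analysis_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0) {
    .stopf("unknown configuration key(s): %s", paste(bad, collapse = ", "))
  }
  do.call(analysis_config, vals)
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("<analysis_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-28s %s\n", nm,
                if (is.null(x[[nm]])) "NULL" else format(x[[nm]])))
  }
  invisible(x)
}

# Activity window in minutes (default 1080 = 18 h).
window_minutes <- function(config) {
  as.integer((config$activity_window_end_hour -
                config$activity_window_start_hour) * 60)
}

# sample_stream ---------------------------------------------------------------

#' Construct a validated per-patient sensor stream
#'
#' A sample stream holds one patient's minute-resolution smartwatch epochs:
#' step counts, distance walked (meters), standing-up events, and an optional
#' heart-rate sample. Timestamps must be strictly increasing with at most one
#' epoch per minute; a minute with no epoch means the watch recorded nothing
#' for that minute.
#'
#' @param patient_id Opaque patient identifier (string).
#' @param epochs Data frame with columns \code{timestamp} (POSIXct, minute
#'   resolution), \code{steps}, \code{distance_m}, \code{standup_events},
#'   \code{heart_rate_bpm} (\code{NA} = absent).
#' @return An object of class \code{sample_stream}.
#' @export
sample_stream <- function(patient_id, epochs) {
  epochs <- as_tibble(epochs)
  needed <- c("timestamp", "steps", "distance_m", "standup_events",
              "heart_rate_bpm")
  missing_cols <- setdiff(needed, names(epochs))
  if (length(missing_cols) > 0) {
    .stopf("epochs lack column(s): %s", paste(missing_cols, collapse = ", "))
  }
  epochs <- epochs[needed]
  epochs$timestamp <- as.POSIXct(epochs$timestamp, tz = .TZ)
  for (col in c("steps", "distance_m", "standup_events", "heart_rate_bpm")) {
    epochs[[col]] <- as.numeric(epochs[[col]])
  }
  x <- structure(list(patient_id = as.character(patient_id), epochs = epochs),
                 class = "sample_stream")
  validate_sample_stream(x)
}

#' @rdname sample_stream
#' @param x A \code{sample_stream}.
#' @export
validate_sample_stream <- function(x) {
  e <- x$epochs
  if (nrow(e) == 0) return(x)
  mins <- .minute_index(e$timestamp)
  if (any(diff(mins) <= 0)) {
    i <- which(diff(mins) <= 0)[1]
    if (mins[i + 1] == mins[i]) {
      .stopf("duplicate epoch minute for patient %s at %s",
             x$patient_id, format(e$timestamp[i + 1], "%Y-%m-%d %H:%M"))
    }
    .stopf("epoch timestamps out of order for patient %s at row %d",
           x$patient_id, i + 1)
  }
  if (any(e$steps < 0, na.rm = TRUE) ||
      any(e$distance_m < 0, na.rm = TRUE) ||
      any(e$standup_events < 0, na.rm = TRUE)) {
    .stopf("negative activity count in stream for patient %s", x$patient_id)
  }
  if (any(is.na(e$steps)) || any(is.na(e$distance_m)) ||
      any(is.na(e$standup_events))) {
    .stopf("activity counts must not be missing (patient %s); drop the epoch instead",
           x$patient_id)
  }
  hr <- e$heart_rate_bpm
  if (any(!is.na(hr) & (hr <= 20 | hr >= 250))) {
    .stopf("heart rate outside (20, 250) bpm for patient %s", x$patient_id)
  }
  x
}

#' @export
print.sample_stream <- function(x, ...) {
  cat(sprintf("<sample_stream> patient %s: %d epochs", x$patient_id,
              nrow(x$epochs)))
  if (nrow(x$epochs) > 0) {
    cat(sprintf(" (%s .. %s)", format(min(x$epochs$timestamp)),
                format(max(x$epochs$timestamp))))
  }
  cat("\n")
  invisible(x)
}

.EPOCH_COLS <- readr::cols(
  timestamp = readr::col_character(),
  steps = readr::col_double(),
  distance_m = readr::col_double(),
  standup_events = readr::col_double(),
  heart_rate_bpm = readr::col_double()
)

#' Read a per-patient sensor stream from CSV
#'
#' The file must have columns \code{timestamp,steps,distance_m,
#' standup_events,heart_rate_bpm} with ISO-8601 timestamps. Empty heart-rate
#' cells become absent (\code{NA}); no row is ever silently dropped —
#' malformed rows raise an error naming the row.
#'
#' @param path CSV file path.
#' @param patient_id Patient identifier to attach to the stream.
#' @return A \code{\link{sample_stream}}.
#' @export
read_sample_stream <- function(path, patient_id) {
  raw <- readr::read_csv(path, col_types = .EPOCH_COLS, progress = FALSE)
  ts <- .parse_dt(raw$timestamp)
  bad <- which(is.na(ts) | is.na(raw$timestamp))
  if (length(bad) > 0) {
    .stopf("malformed timestamp in %s at data row %d: '%s'",
           path, bad[1], raw$timestamp[bad[1]])
  }
  raw$timestamp <- ts
  sample_stream(patient_id, raw)
}

#' Write a sensor stream to CSV (inverse of \code{read_sample_stream})
#'
#' @param stream A \code{sample_stream}.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_sample_stream <- function(stream, path) {
  e <- stream$epochs
  out <- tibble(
    timestamp = format(e$timestamp, "%Y-%m-%dT%H:%M:%S", tz = .TZ),
    steps = e$steps,
    distance_m = e$distance_m,
    standup_events = e$standup_events,
    heart_rate_bpm = e$heart_rate_bpm
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

# inhalation sessions ---------------------------------------------------------

#' Read a nebulizer inhalation log from CSV
#'
#' Expects columns \code{start,end,complete,dose_ug}. Sessions are returned
#' sorted by start time. Sessions with \code{end <= start} or duration over
#' 60 minutes are rejected with an error (the nebulizer cannot run a session
#' that long).
#'
#' @param path CSV file path.
#' @param patient_id Patient identifier attached to every session.
#' @return A tibble with columns \code{patient_id, start, end, complete,
#'   dose_ug} (one row per session).
#' @export
read_inhalation_log <- function(path, patient_id) {
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      start = readr::col_character(),
      end = readr::col_character(),
      complete = readr::col_logical(),
      dose_ug = readr::col_double()
    ),
    progress = FALSE
  )
  sessions <- tibble(
    patient_id = as.character(patient_id),
    start = .parse_dt(raw$start),
    end = .parse_dt(raw$end),
    complete = raw$complete,
    dose_ug = raw$dose_ug
  )
  validate_inhalation_sessions(sessions)
}

#' Validate a table of inhalation sessions
#'
#' @param sessions Tibble as returned by \code{\link{read_inhalation_log}}.
#' @return The sessions, sorted by patient and start time.
#' @export
validate_inhalation_sessions <- function(sessions) {
  sessions <- as_tibble(sessions)
  if (any(is.na(sessions$start)) || any(is.na(sessions$end))) {
    .stopf("malformed session timestamp at row %d",
           which(is.na(sessions$start) | is.na(sessions$end))[1])
  }
  dur_min <- as.numeric(difftime(sessions$end, sessions$start, units = "mins"))
  if (any(dur_min <= 0)) {
    .stopf("inhalation session end at or before start (row %d)",
           which(dur_min <= 0)[1])
  }
  if (any(dur_min > 60)) {
    .stopf("inhalation session longer than 60 minutes (row %d)",
           which(dur_min > 60)[1])
  }
  if (any(!is.na(sessions$dose_ug) & sessions$dose_ug <= 0)) {
    .stopf("dose_ug must be positive")
  }
  arrange(sessions, .data$patient_id, .data$start)
}

#' Write an inhalation log to CSV
#'
#' @param sessions Session tibble (one patient).
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_inhalation_log <- function(sessions, path) {
  out <- tibble(
    start = format(sessions$start, "%Y-%m-%dT%H:%M:%S", tz = .TZ),
    end = format(sessions$end, "%Y-%m-%dT%H:%M:%S", tz = .TZ),
    complete = sessions$complete,
    dose_ug = sessions$dose_ug
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

# visit records ---------------------------------------------------------------

.VISIT_LEVELS <- c("initial", "final")
.WHO_FC_LEVELS <- c("I", "II", "III", "IV")

#' Read clinical visit records from CSV
#'
#' One row per patient-visit with columns \code{patient_id, visit,
#' six_mwd_m, borg, who_fc, bnp_ng_l, ntprobnp_ng_l, eq5d_index,
#' psqi_global}. Empty cells become absent (\code{NA}), never zero.
#' Duplicate (patient, visit) pairs are an error; a patient reporting both
#' BNP and NT-proBNP at one visit triggers a warning (sites conventionally
#' measure one or the other).
#'
#' @param path CSV file path.
#' @return A validated tibble of visit records.
#' @export
read_visits <- function(path) {
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      patient_id = readr::col_character(),
      visit = readr::col_character(),
      six_mwd_m = readr::col_double(),
      borg = readr::col_double(),
      who_fc = readr::col_character(),
      bnp_ng_l = readr::col_double(),
      ntprobnp_ng_l = readr::col_double(),
      eq5d_index = readr::col_double(),
      psqi_global = readr::col_double()
    ),
    progress = FALSE
  )
  validate_visits(as_tibble(raw))
}

#' Validate a tibble of visit records
#'
#' @param visits Tibble with the columns of \code{\link{read_visits}}.
#' @return The validated tibble.
#' @export
validate_visits <- function(visits) {
  if (!all(visits$visit %in% .VISIT_LEVELS)) {
    .stopf("visit must be one of: %s", paste(.VISIT_LEVELS, collapse = ", "))
  }
  dup <- duplicated(visits[c("patient_id", "visit")])
  if (any(dup)) {
    d <- visits[dup, ][1, ]
    .stopf("duplicate visit record: patient %s, visit %s",
           d$patient_id, d$visit)
  }
  if (any(!is.na(visits$six_mwd_m) & visits$six_mwd_m < 0)) {
    .stopf("six_mwd_m must be nonnegative")
  }
  if (any(!is.na(visits$borg) & (visits$borg < 0 | visits$borg > 10))) {
    .stopf("borg score must lie in [0, 10]")
  }
  if (any(!is.na(visits$who_fc) & !visits$who_fc %in% .WHO_FC_LEVELS)) {
    .stopf("who_fc must be one of I, II, III, IV")
  }
  if (any(!is.na(visits$eq5d_index) &
          (visits$eq5d_index < -0.6 | visits$eq5d_index > 1.0))) {
    .stopf("eq5d_index must lie in [-0.6, 1.0]")
  }
  if (any(!is.na(visits$psqi_global) &
          (visits$psqi_global < 0 | visits$psqi_global > 21 |
             visits$psqi_global != round(visits$psqi_global)))) {
    .stopf("psqi_global must be an integer in [0, 21]")
  }
  if (any(!is.na(visits$bnp_ng_l) & visits$bnp_ng_l < 0) ||
      any(!is.na(visits$ntprobnp_ng_l) & visits$ntprobnp_ng_l < 0)) {
    .stopf("natriuretic peptide levels must be nonnegative")
  }
  both <- !is.na(visits$bnp_ng_l) & !is.na(visits$ntprobnp_ng_l)
  if (any(both)) {
    rlang::warn(sprintf(
      "patient %s reports both BNP and NT-proBNP at one visit",
      visits$patient_id[both][1]))
  }
  visits
}

#' Write visit records to CSV
#'
#' @param visits Visit tibble.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_visits <- function(visits, path) {
  readr::write_csv(visits, path, na = "", progress = FALSE)
  invisible(path)
}

# study timeline --------------------------------------------------------------

#' Read per-patient study timelines from CSV
#'
#' Columns: \code{patient_id, enrollment_date, treatment_start,
#' observation_end}. \code{treatment_start} is the date-time of the first
#' inhalation; the baseline period covers calendar days strictly before its
#' date and the observation period runs from that date to
#' \code{observation_end} inclusive.
#'
#' @param path CSV file path.
#' @return A validated timeline tibble.
#' @export
read_timeline <- function(path) {
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      patient_id = readr::col_character(),
      enrollment_date = readr::col_date(),
      treatment_start = readr::col_character(),
      observation_end = readr::col_date()
    ),
    progress = FALSE
  )
  raw$treatment_start <- .parse_dt(raw$treatment_start)
  validate_timeline(as_tibble(raw))
}

#' Validate a timeline tibble
#'
#' @param timeline Tibble with the columns of \code{\link{read_timeline}}.
#' @return The validated tibble.
#' @export
validate_timeline <- function(timeline) {
  if (any(duplicated(timeline$patient_id))) {
    .stopf("duplicate timeline for patient %s",
           timeline$patient_id[duplicated(timeline$patient_id)][1])
  }
  tsd <- .date_of(timeline$treatment_start)
  if (any(tsd < timeline$enrollment_date)) {
    .stopf("treatment_start before enrollment_date")
  }
  if (any(timeline$observation_end <= tsd)) {
    .stopf("observation_end must fall after the treatment start date")
  }
  timeline
}

#' Write a timeline tibble to CSV
#'
#' @param timeline Timeline tibble.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_timeline <- function(timeline, path) {
  out <- tibble(
    patient_id = timeline$patient_id,
    enrollment_date = format(timeline$enrollment_date, "%Y-%m-%d"),
    treatment_start = format(timeline$treatment_start, "%Y-%m-%dT%H:%M:%S",
                             tz = .TZ),
    observation_end = format(timeline$observation_end, "%Y-%m-%d")
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
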