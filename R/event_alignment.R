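# Event-aligned post-inhalation activity curves and inhalation-behavior
# summaries.
#
# For every inhalation session, 12 consecutive 15-minute bins start at the
# session's end (rounded up to the next whole minute when the session ends
# mid-minute). A bin's value is the summed activity over its worn minutes.
# A session is excluded when any minute of bins 2..12 is unworn — i.e. the
# watch was not worn over (essentially) the whole 3 hours after inhalation;
# the first bin tolerates partial wear and its raw sum is used unscaled.
# `strict_wear_exclusion = TRUE` extends the rule to the first bin.
# Overlapping 3-hour windows of nearby sessions each contribute
# independently. Averaging is three-level: bins are averaged over a
# patient-day's included sessions, then patient-day curves are averaged
# over all patient-days.

#' Bin post-inhalation activity for each session of one patient
#'
#' @param stream A \code{\link{sample_stream}}.
#' @param sessions Session tibble for the same patient (see
#'   \code{\link{read_inhalation_log}}).
#' @param config An \code{\link{analysis_config}}.
#' @param measure Activity measure to bin: \code{"distance_m"} or
#'   \code{"steps"}.
#' @return Tibble with one row per session: \code{patient_id, date} (the
#'   calendar date of the session's end, which is the day the session is
#'   attributed to), \code{start, end, included, reason} (\code{NA} when
#'   included, else \code{"wear_gap"} or \code{"beyond_coverage"}),
#'   \code{partial_first_bin}, and bin columns \code{bin_1 .. bin_n}.
#' @export
align_sessions <- function(stream, sessions, config = analysis_config(),
                           measure = c("distance_m", "steps")) {
  measure <- match.arg(measure)
  stopifnot(all(sessions$patient_id == stream$patient_id))
  n_bins <- config$n_bins
  horizon <- n_bins * config$bin_minutes
  e <- stream$epochs
  keys <- .minute_index(e$timestamp)
  worn <- .worn(e)
  vals <- e[[if (measure == "steps") "steps" else "distance_m"]]
  max_key <- if (length(keys)) max(keys) else -Inf

  n_s <- nrow(sessions)
  bin_names <- paste0("bin_", seq_len(n_bins))
  if (n_s == 0) {
    out <- tibble(patient_id = character(0), date = as.Date(character(0)),
                  start = as.POSIXct(character(0), tz = .TZ),
                  end = as.POSIXct(character(0), tz = .TZ),
                  included = logical(0), reason = character(0),
                  partial_first_bin = logical(0))
    out[bin_names] <- lapply(bin_names, function(b) numeric(0))
    return(out)
  }

  # first whole minute at/after session end
  end_min <- ceiling(as.numeric(sessions$end) / 60)
  idx <- outer(end_min, 0:(horizon - 1), `+`)        # n_s x horizon
  pos <- match(as.vector(idx), keys)
  worn_mat <- matrix(!is.na(pos) & worn[pos], nrow = n_s)
  val_mat <- matrix(ifelse(is.na(pos), 0, vals[pos]), nrow = n_s)
  val_mat[!worn_mat] <- 0

  # indicator of bin membership: horizon x n_bins
  binmap <- outer(seq_len(horizon),
                  seq_len(n_bins),
                  function(m, b) as.numeric((m - 1) %/% config$bin_minutes ==
                                              b - 1))
  bin_sums <- val_mat %*% binmap
  unworn_bins <- (1 - worn_mat) %*% binmap            # unworn minutes per bin

  check_bins <- if (config$strict_wear_exclusion) seq_len(n_bins) else
    seq_len(n_bins)[-1]
  gap <- rowSums(unworn_bins[, check_bins, drop = FALSE]) > 0
  beyond <- end_min + horizon - 1 > max_key
  reason <- ifelse(gap & beyond, "beyond_coverage",
                   ifelse(gap, "wear_gap", NA_character_))
  included <- !gap
  partial_first <- included & unworn_bins[, 1] > 0

  out <- tibble(
    patient_id = sessions$patient_id,
    date = .date_of(sessions$end),
    start = sessions$start,
    end = sessions$end,
    included = included,
    reason = reason,
    partial_first_bin = partial_first
  )
  colnames(bin_sums) <- bin_names
  dplyr::bind_cols(out, as_tibble(bin_sums))
}

#' Align sessions for a whole cohort
#'
#' @param streams Named list of \code{\link{sample_stream}}s.
#' @param sessions Session tibble for all patients.
#' @param config An \code{\link{analysis_config}}.
#' @param measure Activity measure to bin.
#' @return Row-bound per-session alignment tibble (see
#'   \code{\link{align_sessions}}).
#' @export
align_cohort <- function(streams, sessions, config = analysis_config(),
                         measure = c("distance_m", "steps")) {
  measure <- match.arg(measure)
  purrr::map_dfr(names(streams), function(pid) {
    align_sessions(streams[[pid]],
                   sessions[sessions$patient_id == pid, , drop = FALSE],
                   config, measure)
  })
}

#' Three-level average of aligned session curves
#'
#' Included sessions are first averaged bin-wise within each patient-day;
#' the resulting patient-day curves are then averaged bin-wise over all
#' patient-days to give the cohort curve.
#'
#' @param aligned Per-session alignment tibble from
#'   \code{\link{align_sessions}} or \code{\link{align_cohort}}.
#' @param measure Label recorded on the result.
#' @return An object of class \code{aligned_activity_curve}: a list with
#'   \code{cohort_means} (length \code{n_bins}), \code{patient_day_curves}
#'   (tibble with \code{patient_id, date, n_sessions} and bin columns),
#'   \code{included_inhalations}, \code{excluded_inhalations},
#'   \code{partial_first_bin_count}, \code{n_patient_days}, \code{n_bins},
#'   \code{bin_minutes}.
#' @export
average_curves <- function(aligned, measure = "distance_m") {
  bin_names <- grep("^bin_", names(aligned), value = TRUE)
  inc <- aligned[aligned$included, , drop = FALSE]
  if (nrow(inc) == 0) {
    .stopf("no included inhalation sessions: cannot form an aligned curve")
  }
  pd <- inc |>
    group_by(patient_id = .data$patient_id, date = .data$date) |>
    summarise(n_sessions = dplyr::n(),
              across(all_of(bin_names), mean), .groups = "drop")
  cohort_means <- colMeans(as.matrix(pd[bin_names]))
  bin_minutes <- attr(aligned, "bin_minutes")
  structure(
    list(
      measure = measure,
      n_bins = length(bin_names),
      bin_minutes = bin_minutes %||% 15L,
      cohort_means = unname(cohort_means),
      patient_day_curves = pd,
      included_inhalations = sum(aligned$included),
      excluded_inhalations = sum(!aligned$included),
      partial_first_bin_count = sum(aligned$partial_first_bin),
      n_patient_days = nrow(pd)
    ),
    class = "aligned_activity_curve"
  )
}

#' @export
print.aligned_activity_curve <- function(x, ...) {
  cat(sprintf(
    "<aligned_activity_curve> %s: %d bins x %d min, %d patient-days\n",
    x$measure, x$n_bins, x$bin_minutes, x$n_patient_days))
  cat(sprintf("  sessions included %d, excluded %d, partial first bin %d\n",
              x$included_inhalations, x$excluded_inhalations,
              x$partial_first_bin_count))
  cat("  cohort means:", paste(signif(x$cohort_means, 4), collapse = " "),
      "\n")
  invisible(x)
}

#' Turn an aligned curve into a tidy tibble
#'
#' @param x An \code{aligned_activity_curve}.
#' @param ... Unused.
#' @return Tibble: \code{bin, offset_min, mean_value, n_patient_days}.
#' @exportS3Method tibble::as_tibble
as_tibble.aligned_activity_curve <- function(x, ...) {
  tibble(
    bin = seq_len(x$n_bins),
    offset_min = (seq_len(x$n_bins) - 1) * x$bin_minutes,
    mean_value = x$cohort_means,
    n_patient_days = x$n_patient_days
  )
}

#' Inhalation-behavior summaries
#'
#' Sessions are attributed to the calendar date of their end time and
#' restricted to each patient's observation period (treatment-start date
#' through observation end). Observation days without any session count as
#' zero-session days in the daily-count statistics but do not enter the
#' duration or percent-complete statistics.
#'
#' @param sessions Session tibble for the cohort.
#' @param timeline Timeline tibble.
#' @return A list with \code{per_patient} (one row per patient:
#'   \code{median_daily_sessions, mean_daily_sessions,
#'   median_daily_duration_min, median_daily_pct_complete, n_days,
#'   n_sessions}) and \code{cohort} (per statistic: median, q1, q3 over
#'   patients). Patients with no sessions are reported with absent values.
#' @export
inhalation_behavior <- function(sessions, timeline) {
  per_patient <- purrr::map_dfr(timeline$patient_id, function(pid) {
    tl <- timeline[timeline$patient_id == pid, ]
    obs_dates <- seq(.date_of(tl$treatment_start), tl$observation_end,
                     by = "day")
    s <- sessions[sessions$patient_id == pid, , drop = FALSE]
    s <- s[.date_of(s$end) %in% obs_dates, , drop = FALSE]
    if (nrow(s) == 0) {
      return(tibble(patient_id = pid, median_daily_sessions = NA_real_,
                    mean_daily_sessions = NA_real_,
                    median_daily_duration_min = NA_real_,
                    median_daily_pct_complete = NA_real_,
                    n_days = length(obs_dates), n_sessions = 0L))
    }
    dur <- as.numeric(difftime(s$end, s$start, units = "mins"))
    by_day <- tibble(date = .date_of(s$end), dur = dur,
                     complete = s$complete) |>
      group_by(date = .data$date) |>
      summarise(n = dplyr::n(), mean_dur = mean(.data$dur),
                pct_complete = 100 * mean(.data$complete), .groups = "drop")
    counts <- rep(0L, length(obs_dates))
    counts[match(by_day$date, obs_dates)] <- by_day$n
    tibble(
      patient_id = pid,
      median_daily_sessions = stats::median(counts),
      mean_daily_sessions = mean(counts),
      median_daily_duration_min = stats::median(by_day$mean_dur),
      median_daily_pct_complete = stats::median(by_day$pct_complete),
      n_days = length(obs_dates),
      n_sessions = nrow(s)
    )
  })
  stat_cols <- c("median_daily_sessions", "mean_daily_sessions",
                 "median_daily_duration_min", "median_daily_pct_complete")
  cohort <- purrr::map_dfr(stat_cols, function(colname) {
    v <- per_patient[[colname]]
    v <- v[!is.na(v)]
    tibble(
      statistic = colname,
      n = length(v),
      median = if (length(v)) stats::median(v) else NA_real_,
      q1 = if (length(v)) stats::quantile(v, 0.25, names = FALSE) else NA_real_,
      q3 = if (length(v)) stats::quantile(v, 0.75, names = FALSE) else NA_real_
    )
  })
  list(per_patient = per_patient, cohort = cohort)
}
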