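# Digital 6-minute-walk-distance estimation and heart-rate endpoints around
# the 6-minute walk test.
#
# The digital walk distance is an explicit stride model: steps during the
# test times a stride length, either a constant (default 0.78 m, a
# healthy-adult calibration) or a per-patient value. Heart-rate endpoints:
# per-minute change from the minute before the test, chronotropic response
# (peak walking HR minus resting HR), and a post-test recovery curve at
# half-minute offsets (negative values = heart rate dropping).

#' Construct a walk-test trace
#'
#' Per-minute heart-rate samples around one 6-minute walk test, plus the
#' step count accumulated during the test.
#'
#' @param patient_id Patient identifier.
#' @param visit \code{"initial"} or \code{"final"}.
#' @param test_start POSIXct start of the test (the test ends exactly 6
#'   minutes later).
#' @param pre_hr Numeric vector of per-minute HR before the start; the last
#'   element is minute −1.
#' @param in_hr Numeric vector of length 6: HR at test minutes 1..6.
#' @param post_hr Numeric vector of per-minute HR after the end (minute
#'   +1, +2, ...); at least 3 minutes are needed for a full recovery curve.
#' @param steps_in_test Nonnegative integer step count, or \code{NA}.
#' @param traditional_distance_m Conventionally measured walk distance, or
#'   \code{NA}.
#' @return An object of class \code{walk_test_trace}.
#' @export
walk_test_trace <- function(patient_id, visit, test_start, pre_hr, in_hr,
                            post_hr, steps_in_test,
                            traditional_distance_m = NA_real_) {
  if (length(in_hr) != 6) .stopf("in_hr must hold exactly 6 per-minute samples")
  if (length(pre_hr) < 1) .stopf("pre_hr must hold at least minute -1")
  hr_all <- c(pre_hr, in_hr, post_hr)
  if (any(!is.na(hr_all) & (hr_all <= 20 | hr_all >= 250))) {
    .stopf("heart rate outside (20, 250) bpm in walk-test trace")
  }
  if (!is.na(steps_in_test) && steps_in_test < 0) {
    .stopf("steps_in_test must be nonnegative")
  }
  structure(
    list(patient_id = as.character(patient_id),
         visit = match.arg(visit, .VISIT_LEVELS),
         test_start = as.POSIXct(test_start, tz = .TZ),
         pre_hr = as.numeric(pre_hr),
         in_hr = as.numeric(in_hr),
         post_hr = as.numeric(post_hr),
         steps_in_test = steps_in_test,
         traditional_distance_m = traditional_distance_m),
    class = "walk_test_trace"
  )
}

#' @export
print.walk_test_trace <- function(x, ...) {
  cat(sprintf(
    "<walk_test_trace> patient %s, %s visit: %s steps, pre/in/post HR %d/%d/%d min\n",
    x$patient_id, x$visit,
    ifelse(is.na(x$steps_in_test), "?", x$steps_in_test),
    length(x$pre_hr), length(x$in_hr), length(x$post_hr)))
  invisible(x)
}

#' Digital 6-minute walk distance
#'
#' \code{steps_in_test * stride}: the stride is the per-patient value when
#' supplied, otherwise the constant \code{config$stride_length_m}.
#'
#' @param trace A \code{\link{walk_test_trace}}.
#' @param config An \code{\link{analysis_config}}.
#' @param stride_m Optional per-patient stride length in meters.
#' @return Distance in meters, or \code{NA} when steps are absent.
#' @export
digital_6mwd <- function(trace, config = analysis_config(), stride_m = NULL) {
  if (is.na(trace$steps_in_test)) return(NA_real_)
  stride <- stride_m %||% config$stride_length_m
  trace$steps_in_test * stride
}

#' Per-minute heart-rate change during the walk test
#'
#' Change at test minute k is \code{HR(minute k) - HR(minute -1)}.
#'
#' @param trace A \code{\link{walk_test_trace}}.
#' @return Numeric vector of length 6, or all-\code{NA} when the minute −1
#'   sample is missing.
#' @export
hr_during_test <- function(trace) {
  ref <- tail(trace$pre_hr, 1)
  if (is.na(ref)) return(rep(NA_real_, 6))
  trace$in_hr - ref
}

#' Resting heart rate
#'
#' Mean heart rate over worn minutes with zero steps. For a
#' \code{\link{sample_stream}} this is computed over the activity window of
#' one date (the daily resting HR); for a \code{\link{walk_test_trace}} it
#' is the mean of the \code{config$resting_hr_window_min} pre-test minutes,
#' which are taken to be at rest. Absent when fewer than
#' \code{config$resting_hr_window_min} qualifying minutes exist.
#'
#' @param x A \code{sample_stream} or \code{walk_test_trace}.
#' @param ... Passed to methods.
#' @return Resting HR in bpm, or \code{NA}.
#' @export
resting_hr <- function(x, ...) UseMethod("resting_hr")

#' @rdname resting_hr
#' @param date Date for the daily resting HR.
#' @param config An \code{\link{analysis_config}}.
#' @export
resting_hr.sample_stream <- function(x, date, config = analysis_config(),
                                     ...) {
  e <- x$epochs
  keep <- .date_of(e$timestamp) == as.Date(date) &
    .in_window(e$timestamp, config) & .worn(e) & e$steps == 0
  if (sum(keep) < config$resting_hr_window_min) return(NA_real_)
  mean(e$heart_rate_bpm[keep])
}

#' @rdname resting_hr
#' @export
resting_hr.walk_test_trace <- function(x, config = analysis_config(), ...) {
  w <- config$resting_hr_window_min
  pre <- x$pre_hr[!is.na(x$pre_hr)]
  if (length(pre) < w) return(NA_real_)
  mean(tail(pre, w))
}

#' Chronotropic response
#'
#' Peak walking heart rate minus resting heart rate, a marker of
#' physiological reserve.
#'
#' @param trace A \code{\link{walk_test_trace}}.
#' @param config An \code{\link{analysis_config}}.
#' @param resting Optional resting HR override; defaults to
#'   \code{resting_hr(trace, config)}.
#' @return Response in bpm, or \code{NA} when resting HR is unavailable.
#' @export
chronotropic_response <- function(trace, config = analysis_config(),
                                  resting = NULL) {
  resting <- resting %||% resting_hr(trace, config)
  if (is.na(resting) || all(is.na(trace$in_hr))) return(NA_real_)
  max(trace$in_hr, na.rm = TRUE) - resting
}

#' Post-test heart-rate recovery curve
#'
#' Values \code{HR(end + t) - HR(end)} at offsets \code{t = 0.5, 1, ..., 3}
#' minutes; HR at the end of the test is the minute-6 sample. Whole-minute
#' offsets use the post-test samples directly; half-minute offsets use
#' linear interpolation on the minute grid. Negative values mean the heart
#' rate is dropping (recovering). If fewer than 3 post-test minutes are
#' available the curve is truncated to the offsets that can be evaluated.
#'
#' @param trace A \code{\link{walk_test_trace}}.
#' @param offsets_min Offsets (minutes) at which to evaluate; default
#'   \code{seq(0.5, 3, by = 0.5)}.
#' @return Named numeric vector of HR changes at the evaluable offsets.
#' @export
recovery_curve <- function(trace, offsets_min = seq(0.5, 3, by = 0.5)) {
  end_hr <- trace$in_hr[6]
  post <- trace$post_hr
  grid_t <- c(0, seq_along(post))
  grid_hr <- c(end_hr, post)
  ok <- !is.na(grid_hr)
  eval_at <- offsets_min[offsets_min <= max(grid_t[ok])]
  if (length(eval_at) == 0 || sum(ok) < 2) {
    return(setNames(numeric(0), character(0)))
  }
  hr_t <- stats::approx(grid_t[ok], grid_hr[ok], xout = eval_at)$y
  setNames(hr_t - end_hr, paste0("t", as.character(eval_at)))
}

#' All walk-test endpoints for one trace
#'
#' @param trace A \code{\link{walk_test_trace}}.
#' @param config An \code{\link{analysis_config}}.
#' @param stride_m Optional per-patient stride length.
#' @return A list of class \code{walk_test_endpoints}:
#'   \code{digital_6mwd_m}, \code{resting_hr_bpm},
#'   \code{per_minute_hr_change}, \code{chronotropic_response_bpm},
#'   \code{recovery_curve}.
#' @export
walk_test_endpoints <- function(trace, config = analysis_config(),
                                stride_m = NULL) {
  rest <- resting_hr(trace, config)
  structure(
    list(
      patient_id = trace$patient_id,
      visit = trace$visit,
      digital_6mwd_m = digital_6mwd(trace, config, stride_m),
      resting_hr_bpm = rest,
      per_minute_hr_change = hr_during_test(trace),
      chronotropic_response_bpm = chronotropic_response(trace, config,
                                                        resting = rest),
      recovery_curve = recovery_curve(trace)
    ),
    class = "walk_test_endpoints"
  )
}

# trace I/O -------------------------------------------------------------------

#' Write walk-test traces to a directory
#'
#' Writes \code{traces.csv} (patient_id, visit, phase, minute, hr_bpm; the
#' minute column counts ... −2, −1 for the pre phase, 1..6 for the test
#' phase, 1, 2, ... for the post phase) and \code{walktests.csv}
#' (patient_id, visit, test_start, steps_in_test, traditional_distance_m).
#'
#' @param traces List of \code{\link{walk_test_trace}} objects.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_walk_traces <- function(traces, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- purrr::map_dfr(traces, function(tr) {
    bind_rows(
      tibble(patient_id = tr$patient_id, visit = tr$visit, phase = "pre",
             minute = seq(-length(tr$pre_hr), -1), hr_bpm = tr$pre_hr),
      tibble(patient_id = tr$patient_id, visit = tr$visit, phase = "test",
             minute = 1:6, hr_bpm = tr$in_hr),
      tibble(patient_id = tr$patient_id, visit = tr$visit, phase = "post",
             minute = seq_along(tr$post_hr), hr_bpm = tr$post_hr)
    )
  })
  idx <- purrr::map_dfr(traces, function(tr) {
    tibble(patient_id = tr$patient_id, visit = tr$visit,
           test_start = format(tr$test_start, "%Y-%m-%dT%H:%M:%S", tz = .TZ),
           steps_in_test = tr$steps_in_test,
           traditional_distance_m = tr$traditional_distance_m)
  })
  readr::write_csv(rows, file.path(dir, "traces.csv"), na = "",
                   progress = FALSE)
  readr::write_csv(idx, file.path(dir, "walktests.csv"), na = "",
                   progress = FALSE)
  invisible(dir)
}

#' Read walk-test traces written by \code{\link{write_walk_traces}}
#'
#' @param dir Directory holding \code{traces.csv} and \code{walktests.csv}.
#' @return List of \code{\link{walk_test_trace}} objects, named
#'   \code{"<patient>.<visit>"}.
#' @export
read_walk_traces <- function(dir) {
  rows <- readr::read_csv(
    file.path(dir, "traces.csv"),
    col_types = readr::cols(patient_id = readr::col_character(),
                            visit = readr::col_character(),
                            phase = readr::col_character(),
                            minute = readr::col_integer(),
                            hr_bpm = readr::col_double()),
    progress = FALSE)
  idx <- readr::read_csv(
    file.path(dir, "walktests.csv"),
    col_types = readr::cols(patient_id = readr::col_character(),
                            visit = readr::col_character(),
                            test_start = readr::col_character(),
                            steps_in_test = readr::col_double(),
                            traditional_distance_m = readr::col_double()),
    progress = FALSE)
  traces <- purrr::pmap(idx, function(patient_id, visit, test_start,
                                      steps_in_test,
                                      traditional_distance_m) {
    sub <- rows[rows$patient_id == patient_id & rows$visit == visit, ]
    walk_test_trace(
      patient_id, visit,
      .parse_dt(test_start),
      pre_hr = sub$hr_bpm[sub$phase == "pre"][order(sub$minute[sub$phase == "pre"])],
      in_hr = sub$hr_bpm[sub$phase == "test"][order(sub$minute[sub$phase == "test"])],
      post_hr = sub$hr_bpm[sub$phase == "post"][order(sub$minute[sub$phase == "post"])],
      steps_in_test = steps_in_test,
      traditional_distance_m = traditional_distance_m
    )
  })
  names(traces) <- paste(idx$patient_id, idx$visit, sep = ".")
  traces
}
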