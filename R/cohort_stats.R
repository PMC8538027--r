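# Cohort-level change-score statistics: the change table, pairwise-complete
# Pearson correlations, and change-on-change regressions.
#
# Analyses are exploratory and descriptive: bare correlation coefficients
# with per-pair n accounting, no multiplicity adjustment, and no confidence
# intervals unless the seeded bootstrap is requested. Missing cells are
# never imputed; each correlation uses the rows where both members of the
# pair are observed. BNP and NT-proBNP stay separate columns — sites
# measure one or the other, never pooled.

.TRADITIONAL_CHANGE_COLS <- c("d_six_mwd_m", "d_borg", "d_bnp_ng_l",
                              "d_ntprobnp_ng_l", "d_eq5d_index",
                              "d_psqi_global", "d_resting_hr_bpm")
.DIGITAL_CHANGE_COLS <- c("d_daily_distance_m", "d_daily_steps",
                          "d_daily_standups", "d_digital_6mwd_m")

#' Tabulate walk-test endpoints for a set of traces
#'
#' @param traces List of \code{\link{walk_test_trace}} objects.
#' @param config An \code{\link{analysis_config}}.
#' @param strides Optional named numeric vector of per-patient stride
#'   lengths (meters); unnamed patients use the constant stride.
#' @return Tibble: \code{patient_id, visit, digital_6mwd_m,
#'   resting_hr_bpm, chronotropic_response_bpm}.
#' @export
endpoints_table <- function(traces, config = analysis_config(),
                            strides = NULL) {
  purrr::map_dfr(traces, function(tr) {
    ep <- walk_test_endpoints(tr, config,
                              stride_m = strides[[tr$patient_id]] %||% NULL)
    tibble(patient_id = tr$patient_id, visit = tr$visit,
           digital_6mwd_m = ep$digital_6mwd_m,
           resting_hr_bpm = ep$resting_hr_bpm,
           chronotropic_response_bpm = ep$chronotropic_response_bpm)
  })
}

#' Assemble the per-patient change table
#'
#' One row per full-analysis-set patient. Traditional changes are
#' final-minus-initial visit values; activity changes come from the
#' baseline/end period summaries; the digital walk-distance change comes
#' from the walk-test endpoints. Absence propagates — a patient missing a
#' visit value has an absent cell, never zero. A full-analysis-set patient
#' missing every input keeps an all-absent row.
#'
#' @param changes Period-change tibble from
#'   \code{\link{change_from_baseline}} (measures \code{distance},
#'   \code{steps}, \code{standups}, \code{resting_hr}).
#' @param visits Visit-record tibble.
#' @param walk_tbl Endpoint tibble from \code{\link{endpoints_table}}, or
#'   \code{NULL} when no traces exist.
#' @param membership Membership tibble from
#'   \code{\link{full_analysis_filter}}.
#' @return Tibble with columns \code{patient_id},
#'   \code{d_six_mwd_m, d_borg, d_bnp_ng_l, d_ntprobnp_ng_l, d_eq5d_index,
#'   d_psqi_global, d_resting_hr_bpm} (traditional) and
#'   \code{d_daily_distance_m, d_daily_steps, d_daily_standups,
#'   d_digital_6mwd_m} (digital).
#' @export
build_change_table <- function(changes, visits, walk_tbl = NULL,
                               membership) {
  pids <- membership$patient_id[membership$in_full_set]
  visit_change <- function(pid, col) {
    vi <- visits[visits$patient_id == pid & visits$visit == "initial", ][[col]]
    vf <- visits[visits$patient_id == pid & visits$visit == "final", ][[col]]
    if (length(vi) != 1 || length(vf) != 1) return(NA_real_)
    vf - vi
  }
  period_change <- function(pid, measure) {
    v <- changes$change[changes$patient_id == pid &
                          changes$measure == measure]
    if (length(v) != 1) NA_real_ else v
  }
  walk_change <- function(pid) {
    if (is.null(walk_tbl)) return(NA_real_)
    vi <- walk_tbl$digital_6mwd_m[walk_tbl$patient_id == pid &
                                    walk_tbl$visit == "initial"]
    vf <- walk_tbl$digital_6mwd_m[walk_tbl$patient_id == pid &
                                    walk_tbl$visit == "final"]
    if (length(vi) != 1 || length(vf) != 1) return(NA_real_)
    vf - vi
  }
  purrr::map_dfr(pids, function(pid) {
    tibble(
      patient_id = pid,
      d_six_mwd_m = visit_change(pid, "six_mwd_m"),
      d_borg = visit_change(pid, "borg"),
      d_bnp_ng_l = visit_change(pid, "bnp_ng_l"),
      d_ntprobnp_ng_l = visit_change(pid, "ntprobnp_ng_l"),
      d_eq5d_index = visit_change(pid, "eq5d_index"),
      d_psqi_global = visit_change(pid, "psqi_global"),
      d_resting_hr_bpm = period_change(pid, "resting_hr"),
      d_daily_distance_m = period_change(pid, "distance"),
      d_daily_steps = period_change(pid, "steps"),
      d_daily_standups = period_change(pid, "standups"),
      d_digital_6mwd_m = walk_change(pid)
    )
  })
}

#' Pairwise-complete Pearson correlations between change scores
#'
#' For every (traditional, digital) pair, the sample Pearson correlation is
#' computed over the rows where both cells are present; nothing is imputed.
#' Pairs with fewer than 2 complete rows or a zero-variance member get an
#' absent \code{r} with a note. Pairs with fewer than
#' \code{low_n_threshold} complete rows are flagged — with very few
#' patients a coefficient is not meaningfully interpretable.
#'
#' @param table Change table from \code{\link{build_change_table}} (or any
#'   tibble of numeric columns).
#' @param traditional,digital Column names to correlate.
#' @param low_n_threshold Flag pairs with \code{n_pairs} below this;
#'   default 10.
#' @param complete_cases If \code{TRUE}, restrict to rows complete across
#'   all requested columns before correlating (the planned sensitivity
#'   analysis).
#' @param boot_ci If \code{TRUE}, add seeded bootstrap percentile
#'   confidence intervals.
#' @param n_boot,conf,seed Bootstrap replicates, coverage, and seed.
#' @return Long tibble: \code{traditional, digital, r, n_pairs,
#'   low_n_flag, note} (+ \code{ci_lo, ci_hi} when \code{boot_ci}).
#' @export
pearson_pairwise <- function(table,
                             traditional = intersect(.TRADITIONAL_CHANGE_COLS,
                                                     names(table)),
                             digital = intersect(.DIGITAL_CHANGE_COLS,
                                                 names(table)),
                             low_n_threshold = 10,
                             complete_cases = FALSE,
                             boot_ci = FALSE, n_boot = 1000, conf = 0.95,
                             seed = NULL) {
  if (complete_cases) {
    table <- table[stats::complete.cases(table[c(traditional, digital)]), ,
                   drop = FALSE]
  }
  if (boot_ci && !is.null(seed)) set.seed(seed)
  grid <- tidyr::expand_grid(traditional = traditional, digital = digital)
  purrr::pmap_dfr(grid, function(traditional, digital) {
    x <- table[[traditional]]
    y <- table[[digital]]
    ok <- !is.na(x) & !is.na(y)
    n <- sum(ok)
    r <- NA_real_
    note <- NA_character_
    ci <- c(NA_real_, NA_real_)
    if (n < 2) {
      note <- "fewer than 2 complete pairs"
    } else if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      note <- "zero variance"
    } else {
      r <- stats::cor(x[ok], y[ok])
      if (boot_ci) {
        bs <- replicate(n_boot, {
          i <- sample.int(n, n, replace = TRUE)
          xs <- x[ok][i]; ys <- y[ok][i]
          if (stats::sd(xs) == 0 || stats::sd(ys) == 0) NA_real_
          else stats::cor(xs, ys)
        })
        a <- (1 - conf) / 2
        ci <- stats::quantile(bs, c(a, 1 - a), na.rm = TRUE, names = FALSE)
      }
    }
    out <- tibble(traditional = traditional, digital = digital, r = r,
                  n_pairs = n, low_n_flag = n < low_n_threshold,
                  note = note)
    if (boot_ci) {
      out$ci_lo <- ci[1]
      out$ci_hi <- ci[2]
    }
    out
  })
}

#' Change-on-change ordinary least squares
#'
#' Regresses the change in one traditional clinical measure on changes in
#' digital measures over complete-case rows. Both the joint fit over all
#' predictors and each single-predictor fit are returned.
#'
#' @param table Change table from \code{\link{build_change_table}}.
#' @param dependent Column name of the traditional change score.
#' @param predictors Column names of digital change scores; default
#'   daily distance walked, standing-up events, and digital walk distance.
#' @return A list of class \code{change_regression} with elements
#'   \code{joint} and \code{single} (named by predictor); each fit is a
#'   list \code{(coefficients, r_squared, n)} where \code{coefficients} is
#'   a named vector (intercept first).
#' @export
change_regression <- function(table, dependent,
                              predictors = c("d_daily_distance_m",
                                             "d_daily_standups",
                                             "d_digital_6mwd_m")) {
  fit_one <- function(preds) {
    dat <- table[c(dependent, preds)]
    dat <- dat[stats::complete.cases(dat), , drop = FALSE]
    n <- nrow(dat)
    if (n < length(preds) + 2) {
      .stopf("too few complete cases (%d) to fit %s on %d predictor(s)",
             n, dependent, length(preds))
    }
    fml <- stats::reformulate(preds, response = dependent)
    fit <- stats::lm(fml, data = dat)
    cf <- stats::coef(fit)
    if (any(is.na(cf))) {
      .stopf("rank-deficient fit: collinear predictor(s) %s",
             paste(names(cf)[is.na(cf)], collapse = ", "))
    }
    rss <- sum(stats::residuals(fit)^2)
    tss <- sum((dat[[dependent]] - mean(dat[[dependent]]))^2)
    list(coefficients = cf, r_squared = 1 - rss / tss, n = n)
  }
  structure(
    list(
      dependent = dependent,
      joint = fit_one(predictors),
      single = setNames(lapply(predictors, function(p) fit_one(p)),
                        predictors)
    ),
    class = "change_regression"
  )
}

#' @export
print.change_regression <- function(x, ...) {
  cat(sprintf("<change_regression> %s ~ digital changes\n", x$dependent))
  cat(sprintf("  joint (n=%d, R^2=%.3f):\n", x$joint$n, x$joint$r_squared))
  print(signif(x$joint$coefficients, 4))
  for (p in names(x$single)) {
    s <- x$single[[p]]
    cat(sprintf("  %s alone: slope %.4g, R^2=%.3f, n=%d\n",
                p, s$coefficients[2], s$r_squared, s$n))
  }
  invisible(x)
}
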