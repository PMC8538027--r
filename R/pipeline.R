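# End-to-end orchestration: cohort -> daily activity -> period summaries,
# analysis sets, event-aligned curves, walk-test endpoints, change table,
# correlations.

#' Run the full analysis pipeline on a cohort
#'
#' Convenience wrapper chaining every stage with one configuration. All
#' stages are also exported individually.
#'
#' @param cohort An \code{actistep_cohort} (from
#'   \code{\link{generate_cohort}} or \code{\link{read_cohort}}).
#' @param config An \code{\link{analysis_config}}.
#' @param safety Optional safety-set flags for
#'   \code{\link{full_analysis_filter}}.
#' @param curve_measure Measure for the event-aligned curve.
#' @return A list with elements \code{daily}, \code{baseline}, \code{end},
#'   \code{changes}, \code{cohort_changes}, \code{membership},
#'   \code{aligned}, \code{curve} (\code{NULL} when no session is
#'   includable), \code{behavior}, \code{walk_endpoints},
#'   \code{change_table}, \code{correlations}, \code{wear_tables}.
#' @export
run_pipeline <- function(cohort, config = analysis_config(), safety = NULL,
                         curve_measure = c("distance_m", "steps")) {
  curve_measure <- match.arg(curve_measure)
  daily <- cohort_daily(cohort$streams, cohort$timeline, config)
  baseline <- summarize_baseline(daily, cohort$timeline, config)
  end <- summarize_end(daily, cohort$timeline, config)
  changes <- change_from_baseline(baseline, end)
  membership <- full_analysis_filter(daily, cohort$timeline, cohort$visits,
                                     safety, config)
  aligned <- align_cohort(cohort$streams, cohort$sessions, config,
                          curve_measure)
  curve <- if (any(aligned$included)) {
    average_curves(aligned, curve_measure)
  } else NULL
  behavior <- inhalation_behavior(cohort$sessions, cohort$timeline)
  walk_tbl <- if (length(cohort$traces) > 0) {
    endpoints_table(cohort$traces, config)
  } else NULL
  change_table <- build_change_table(changes, cohort$visits, walk_tbl,
                                     membership)
  correlations <- if (nrow(change_table) >= 2) {
    pearson_pairwise(change_table)
  } else NULL
  wear_tables <- list(
    baseline = wear_use_table(
      filter_to_windows(daily, baseline_window(cohort$timeline, config))),
    end = wear_use_table(
      filter_to_windows(daily, end_window(cohort$timeline, config)))
  )
  list(daily = daily, baseline = baseline, end = end, changes = changes,
       cohort_changes = cohort_change_summary(changes),
       membership = membership, aligned = aligned, curve = curve,
       behavior = behavior, walk_endpoints = walk_tbl,
       change_table = change_table, correlations = correlations,
       wear_tables = wear_tables)
}
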