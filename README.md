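# actistep

Wearable activity and inhalation-behavior endpoints for digitally
monitored pulmonary-hypertension cohorts.

## What it is for

Patients with pulmonary arterial hypertension who add nebulized iloprost to
their therapy can be monitored continuously between clinic visits: a
smartwatch records minute-resolution epochs (steps, distance walked,
standing-up events, heart rate) and the connected nebulizer logs every
inhalation session (start, end, completeness, dose). `actistep` is an
analysis pipeline for such cohorts, aimed at biostatisticians evaluating
digital activity measures against traditional clinical endpoints. It
provides:

* **Ingestion & validation** of sensor streams, inhalation logs, clinical
  visit records and study timelines (plain CSV; nothing silently dropped).
* **Wear-normalized daily activity.** A minute is worn iff its epoch
  carries a heart-rate sample. Daily totals over the 18-hour window
  (6 AM–midnight) are scaled by 1 / wear-fraction; days worn < 10% of the
  window are missing. Per-day mean and resting heart rate ride along.
* **Period summaries and analysis sets.** Baseline = median of ≤ 14 daily
  values before the first inhalation; end = median of the last 14 days of
  observation; change = end − baseline per patient, with the cohort change
  being the median of per-patient changes. A full-analysis-set filter
  (≥ 3 activity days in each period, ≥ 1 clinical outcome at both visits,
  safety-set membership) with per-patient exclusion reasons.
* **Event-aligned curves.** For every inhalation, 12 × 15-minute bins of
  activity starting at session end; sessions with any unworn minute in the
  3-hour tail are excluded (the first bin may be partially worn); bins are
  averaged within patient-day, then across patient-days.
* **Walk-test endpoints.** Digital 6-minute walk distance via an explicit
  stride model (`steps × stride`, constant 0.78 m or per-patient);
  per-minute heart-rate change from minute −1; chronotropic response
  (peak walking HR − resting HR); post-test recovery curve at half-minute
  offsets.
* **Cohort statistics.** Pairwise-complete Pearson correlations between
  traditional and digital change scores (with per-pair n and low-n flags)
  and change-on-change least-squares regressions, joint and per predictor.
* **A seeded synthetic cohort generator** with stored ground truth
  (latent activity levels, treatment effect, boost profile, strides,
  resting heart rates), so the whole pipeline is testable end to end
  without any patient data.

## Worked example

```r
library(actistep)

cohort  <- generate_cohort(cohort_params(rng_seed = 42))  # 18 patients, 91-day observation
results <- run_pipeline(cohort)

results$cohort_changes
#> # A tibble: 4 × 5
#>   measure        n median_change       q1        q3
#>   <chr>      <int>         <dbl>    <dbl>     <dbl>
#> 1 distance      18      934.     553.     1078.
#> 2 resting_hr    18        0.0175  -0.0839    0.0979
#> 3 standups      18        0.566   -2.64      2.35
#> 4 steps         18     1197.     709.     1382.

results$curve
#> <aligned_activity_curve> distance_m: 12 bins x 15 min, 1033 patient-days
#>   sessions included 1999, excluded 6386, partial first bin 162
#>   cohort means: 85.28 84.7 84.34 80.64 78.42 76 74.56 72.39 69.58 66.93 65.41 63.77

subset(results$correlations, traditional == "d_six_mwd_m")
#> # A tibble: 4 × 6
#>   traditional digital                   r n_pairs low_n_flag note
#>   <chr>       <chr>                 <dbl>   <int> <lgl>      <chr>
#> 1 d_six_mwd_m d_daily_distance_m  0.656        18 FALSE      <NA>
#> 2 d_six_mwd_m d_daily_steps       0.656        18 FALSE      <NA>
#> 3 d_six_mwd_m d_daily_standups   -0.00354      18 FALSE      <NA>
#> 4 d_six_mwd_m d_digital_6mwd_m    0.545        18 FALSE      <NA>
```

Reading the output: all 18 synthetic patients qualify for the full
analysis set; the cohort's median daily distance walked rises by about
0.9 km from baseline to the last 14 days (the generator ramps in a
treatment effect plus post-inhalation activity boosts); the event-aligned
curve starts near 85 m per 15 minutes right after inhalation and decays
across the 3-hour horizon (decaying boost on top of the afternoon side of
the circadian profile); and changes in the traditional walk distance
correlate moderately with changes in its digital counterpart and in daily
distance. Distance and step correlations coincide because the simulated
watch converts steps to distance with a fixed stride.

A thin command-line wrapper is installed under `inst/scripts/actistep`:

```sh
actistep simulate --seed 42 -o cohort/
actistep daily cohort/ -o daily.csv
actistep align cohort/ --measure distance_m -o curve.csv
```

## Documentation

The methods vignette (`vignettes/digital-activity-endpoints.Rmd`) explains
the models, parameter defaults and units, the design decisions behind the
wear rule and exclusion logic, what the synthetic cohort does and does not
emulate, and known limitations.
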