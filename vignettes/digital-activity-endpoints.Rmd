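---
title: "Digital activity and inhalation-behavior endpoints: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Digital activity and inhalation-behavior endpoints: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actistep)
```

## The problem

Pulmonary arterial hypertension restricts everyday physical activity, yet
treatment is steered by clinic measurements taken months apart — chiefly the
6-minute walk distance (6MWD), WHO functional class and natriuretic-peptide
levels. When a patient starts nebulized therapy with a connected device, two
continuous data streams become available between visits: minute-resolution
smartwatch epochs (steps, distance, standing-up events, heart rate) and the
nebulizer's inhalation log (session start/end, completeness, dose).
`actistep` turns those streams into analyzable endpoints: normalized daily
activity, event-aligned post-inhalation activity curves, walk-test heart-rate
endpoints, and cohort-level change-from-baseline statistics.

## Wear time and the 18-hour normalization

Consumer wearables are worn intermittently, so raw daily totals confound
activity with wear. The pipeline assumes an 18-hour daily activity window
(6 AM to midnight, wall-clock time) and treats a minute as *worn* iff an
epoch exists for it **and** carries a heart-rate sample. The optical
heart-rate sensor requires skin contact, whereas a step counter can register
off-wrist motion; heart-rate presence is therefore the most conservative
wear proxy available at this resolution.

For each patient-day,

* `wear_fraction` = worn minutes / 1080;
* raw totals are sums over worn minutes inside the window;
* normalized totals are `raw / wear_fraction` — a single global linear
  scale-up, with no within-day circadian re-weighting;
* a day with `wear_fraction < 0.10` is *missing*: its normalized values are
  absent (never zero, never imputed);
* heart rate is averaged over worn minutes, never scaled — it is an
  intensity, not a count.

The linear scale-up is unbiased when wear is unrelated to the activity
pattern; with wear concentrated in active daytime hours it overestimates.
This is a known, deliberate simplification (the acceptance suite verifies
unbiasedness under uniform masking, which is the regime the scale-up is
designed for). Normalization is applied uniformly to distance, steps and
standing-up events; whether the standing-up count should be scaled at all is
ambiguous, and the choice is recorded here rather than hidden.

Activity before 6 AM or after midnight is excluded entirely, not
re-attributed. A daily resting heart rate — the mean over zero-step worn
minutes, reported only when at least `resting_hr_window_min` (default 5)
such minutes exist — rides along with each day.

## Baseline, end of observation, and change

* **Baseline** is the median of non-missing daily values over calendar days
  *strictly before* the date of the first inhalation, restricted to the most
  recent 14 (`baseline_max_days`) days. The treatment-start day itself
  belongs to the observation period.
* **End of observation** is the median over the last 14 (`end_window_days`)
  calendar days of observation.
* **Change** is `end − baseline`, computed per patient and only for
  patients with both values. The cohort change is the *median of
  per-patient changes*, which is not in general the difference of the two
  period medians — a distinction the test suite pins with a three-patient
  fixture whose median change is 1 while the difference of medians is 10.

The full-analysis-set filter admits a patient iff they are in the safety
set (≥1 dose, consent not fully withdrawn), are not a screening failure,
have ≥3 non-missing activity days in the baseline window, ≥3 in the last
two weeks, and at least one clinical outcome (6MWD, BNP or NT-proBNP, or
WHO class) observed at *both* visits. The "last 2 weeks" of the membership
filter is deliberately identified with the 14-day end-summary window: one
window definition, not two subtly different ones. Exclusions carry machine-
readable reason tags.

Cohort medians are reported with type-7 (linear-interpolation) quartiles,
the default of most statistical software; the convention is stated because
nothing in the source data dictates one.

## Event-aligned post-inhalation curves

For every inhalation session, 12 consecutive 15-minute bins begin at the
session's end; a session ending mid-minute snaps up to the next whole
minute, since the epoch grid is 1 minute. A bin's value is the summed
activity over its worn minutes. Averaging is three-level: bins are averaged
over a patient-day's included sessions, the patient-day curves are then
averaged over all patient-days. Nearby sessions produce overlapping 3-hour
windows; each contributes independently, and both complete and incomplete
inhalations enter.

The exclusion rule needs care. "Watch not worn over the entire 3 hours"
is implemented as: a session is excluded iff *any* minute of bins 2–12 is
unworn, while the **first** bin tolerates partial wear; partially covered
first bins are counted (`partial_first_bin_count`) and their raw sums enter
unscaled. This reconciles a strict reading of the 3-hour wear requirement
with the observed existence of first bins at less than full coverage. A
`strict_wear_exclusion` switch extends the rule to the first bin; the
strict mode is what the boost-recovery acceptance check uses, because under
it the first bin's expected content has a clean closed form. Partial bins
are never wear-normalized — normalization belongs to daily totals only.

Sessions are attributed to the calendar date of their end time (the bins
begin there). Inhalation-behavior summaries (daily session counts, mean
daily duration, daily percent complete) count observation days with no
sessions as zero-session days for the count statistics, but such days
contribute nothing to duration or completeness medians.

## Walk-test endpoints

The proprietary stride-length algorithm behind commercial "walked distance"
readouts is unavailable, so the digital 6MWD is an explicit, configurable
stride model: `steps_in_test × stride_length_m`, with the constant default
0.78 m (a healthy-adult calibration) or a per-patient stride. The
healthy-stride default deliberately reproduces the known bias of such
devices — patients with a shortened gait are overestimated — and the
per-patient option quantifies it.

Heart-rate endpoints:

* per-minute change during the test, referenced to the minute −1 sample;
* chronotropic response = peak walking HR − resting HR;
* recovery curve = HR(end + t) − HR(end) for t = 0.5, …, 3 min, with
  whole-minute samples taken directly and half-minute offsets linearly
  interpolated (negative values mean recovery). HR at "end" is the
  minute-6 sample.

"At rest" has no device definition, so resting HR is the mean over
zero-step worn minutes (daily form) or over the 5 pre-test minutes (test
form). The minute grid itself is an assumption: sub-minute cadences must be
pre-binned by the caller.

## Change-score statistics

The change table holds one row per full-analysis-set patient: traditional
changes (6MWD, Borg, BNP, NT-proBNP, EQ-5D index, PSQI, resting HR) and
digital changes (daily distance, steps, stand-ups, digital 6MWD). BNP and
NT-proBNP stay separate — sites measure one or the other — and absence
propagates; nothing is imputed.

Correlations are pairwise-complete Pearson coefficients with per-pair `n`
accounting and a low-n flag below 10 pairs (coefficients on a handful of
patients are not meaningfully interpretable). The analyses are exploratory:
no multiplicity adjustment and no intervals by default; a seeded bootstrap
percentile CI is available behind a flag. A complete-case mode implements
the usual sensitivity analysis. Regressions of a traditional change on
digital changes are ordinary least squares on complete cases; because it is
ambiguous whether such analyses are run jointly or per predictor, both fits
are emitted. Rank deficiency is an error naming the collinear predictors,
not a silent drop.

## The synthetic cohort generator

Patient-level data from wearable studies in this population are not public,
so `generate_cohort()` creates a cohort with known ground truth. Defaults
encode the study-scale conditions: 18 patients; a 4–14-day pre-treatment
baseline; a 91-day observation period; ~5 inhalation sessions/day
(Poisson, placed between 8 AM and 8 PM at least 20 min apart via a spacing
transform that preserves the drawn count); lognormal session durations with
median 5.5 min; 90% complete; patient-level mean wear drawn uniformly from
4.8–11.5 h/day, realized as 2–3 contiguous wear blocks inside the 6
AM–midnight window; median daily (device-reported) distance 5.2 km; resting
heart rate ~76 bpm.

Structural choices worth knowing:

* **Two-state activity.** A minute is "moving" with probability
  `p_active` (0.45); steps in moving minutes are Poisson with rate scaled
  by `1/p_active`, so the expected minute rate is exact while roughly half
  of worn minutes are zero-step resting minutes — without them a daily
  resting heart rate would be unobservable.
* **Circadian profile.** A fixed two-peak (morning / late-afternoon) weight
  curve, normalized to mean 1, makes post-inhalation intervals unevenly
  distributed over the day, as they are in practice. A `"flat"` profile is
  available; tests that need a closed-form expectation (boost recovery,
  treatment-effect recovery) use it, because under the two-peak profile the
  expected bin content depends on the session-time distribution convolved
  with the profile.
* **Boost.** Each session end multiplies the activity rate by
  `1 + A·exp(−t/τ)` (defaults A = 0.20, τ = 60 min), additive across
  overlapping sessions.
* **Treatment effect.** `treatment_effect_km` (default +0.4 km/day) ramps
  linearly over the observation period and is scaled per patient by a
  N(1, 0.6) responder multiplier shared with the visit-record generator, so
  change-score correlations are tunable rather than accidental.
* **Two strides.** The device converts steps to distance with a healthy
  0.78 m stride; patients' true stride averages 0.62 m. Traditional 6MWD
  derives from the latent level; the in-test step count adds 7% lognormal
  measurement error. This reproduces the characteristic pattern of a
  digital walk distance that overestimates the traditional one yet
  correlates moderately with its changes.
* **Seeding.** One seed; per-patient sub-seeds are drawn up front, so
  regeneration is byte-identical file by file.

What the generator does **not** emulate: dropout and consent withdrawal,
device failures and clock drift, seasonal or weekday structure, off-wrist
step artifacts, pharmacokinetics beyond the single exponential boost, and
any dependence of wear on health status. Passing tests therefore show the
*pipeline's* correctness and calibration under controlled conditions — not
that real cohorts satisfy these models.

## Numerical conventions and problem sizes

Degenerate inputs have defined behavior: days outside stream coverage are
zero-wear (missing) days, not errors; a cohort with no includable session
raises an explicit empty-curve error; correlation pairs with under two
complete observations or zero variance are absent with a reason. Medians
use the midpoint convention; bins align at minute resolution with end times
rounded up.

The verification suite sizes were chosen to keep the full run in the
low minutes on one core while leaving Monte-Carlo error well inside each
tolerance: 1000 masked days for normalization unbiasedness (2%), a
3-patient × 10-day minute-enumeration fixture for exact bin equivalence,
50 patients × 90 days for boost recovery (10%) and null flatness (3 SEs),
and 100 random tables against closed-form correlation/regression oracles
(1e−8).

## Limitations

The wear proxy misclassifies worn minutes whose heart-rate reading was
dropped; the linear normalization ignores circadian structure; the
event-aligned curves make no attempt to deconvolve overlapping boosts or
adjust for time-of-day; and the stride model is linear by construction.
These mirror the analysis conventions of the observational design the
package targets, and each is surfaced as a configurable, documented choice
rather than an implicit one.
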