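---
title: "Methods: wearable physiology across pregnancy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wearable physiology across pregnancy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

Finger- and wrist-worn devices record distal body temperature (DBT, °C),
activity (MET), heart rate (HR, bpm), heart-rate variability (HRV, rmssd)
and respiratory rate (RR, rpm) continuously for months. Across a pregnancy
these series carry structure that sparse clinic visits cannot see: the
pre-conception ovulatory temperature cycle, a conception temperature rise,
gradual gestational drifts in every modality, abrupt peridelivery
transitions, and — in pregnancies that end within the first trimester —
a characteristic temperature decline around the time of early fetal loss
(EFL).

`gestwear` implements the full analysis chain for such data: raw-stream
cleaning, daily aggregation, pregnancy alignment, eligibility filtering,
baseline z-scoring, population trajectory profiles, rank-based trimester
statistics, a cumulative multimodal distance statistic, and a time-matched
generalized-estimating-equation (GEE) model of early fetal loss. Because
device data of this kind cannot be redistributed, the package also ships a
seeded synthetic-cohort generator that reproduces the statistical structure
the analysis assumes, making the whole pipeline runnable and testable
without any external data.

## Conventions and alignment

Two survey dates anchor everything: **DKP**, the day the participant
learned of the pregnancy (day 0), and **DPS**, the day the pregnancy
concluded. Conception is modelled at DKP − 28 days, matching the
observation that DKP aligns with 28 days after the most recent trough of
the nightly-maximum temperature (the start of the last menstrual cycle).
All intervals are half-open in days:

| trimester | days (relative to DKP) | length |
|-----------|------------------------|--------|
| −1        | [−91, −28)             | 63     |
| 1         | [−28, 63)              | 91     |
| 2         | [63, 154)              | 91     |
| 3         | [154, 252)             | 98     |
| 4         | [252, 343)             | 91     |

The canonical boundaries {−28, 63, 154, 252} make the first trimester
exactly the printed 91 days; under the half-open convention the third
trimester then spans 98 days, one more than the sometimes-quoted 97 — the
inclusive and half-open day-counting conventions cannot both be satisfied,
so the package fixes the boundary set and documents the one-day
discrepancy rather than guessing. The pre-pregnancy **baseline window** is
[−60, −30) relative to DKP.

## Preprocessing

The cleaning pipeline runs in a fixed order: local-time normalisation and
duplicate removal → 5–95 % per-participant quantile filter → activity
non-wear gate → sleep annotation → 2–98 % per-participant quantile filter
→ daily aggregation.

* **Quantile filters** use linear interpolation of order statistics
  (type 7), computed within a modality (the streams carry different
  physical units, so cross-modality pooling would be meaningless); values
  strictly outside [Q(low), Q(high)] are dropped. The two passes differ
  only in their bounds and in whether a participant's pregnancies are
  pooled.
* **Non-wear gate:** a sample is dropped iff the nearest activity reading
  within ±60 s is strictly below 0.5 MET. The tolerance accommodates the
  different cadences (temperature/MET at 1 min; HR/HRV at 5 min; RR at
  30 s); samples with no nearby MET reading are retained.
* **Daily peak/trough:** the mean of the sample values whose midpoint rank
  (i − ½)/n lies in [0.90, 0.95] (peak) or [0.05, 0.10] (trough). The
  band-*mean* reading is used rather than the mean of the two band-endpoint
  quantiles: for dense minute data the two nearly coincide, and the band
  mean degrades gracefully at small n (falling back to the interpolated
  band-midpoint quantile when no rank lands in the band). The endpoint
  reading remains available via `preprocess_config(peak_definition =
  "endpoint_mean")`.
* **Windows:** aggregates are computed over the civil day ("h24") and the
  fixed nightly clock window [20:00, 08:00) attributed to the evening's
  date. The nightly window deliberately follows the clock, not the
  per-night sleep interval; sleep annotation is carried on the samples but
  does not move the window. Timestamps are naive local times; timezone and
  DST shifts are out of scope.

## Cohort eligibility

Delivered pregnancies are full term iff gestation = (DPS − DKP) + 28 ≥ 259
days (37 weeks). Eligibility requires nightly peak-temperature aggregates
on ≥ 40 % of days in each of trimesters 1–3. Exclusions are applied in
narrative order, one reason per pregnancy (partner-reported surveys,
out-of-window pregnancies, sparse trimesters, other-reason sparsity,
preterm; for the EFL arm: failure to implant, low first-trimester
completeness, low prior-to-pregnancy completeness), and an explicit ledger
records the counts. Two pregnancies from the same participant are retained
as independent analysis units. "Sparse directly around pregnancy onset"
has no numeric definition in the source design, so the synthetic survey
carries those exclusions as explicit flags rather than inventing a rule.

## Normalisation and profiles

Each pregnancy-series is z-scored against its own baseline window,
*z* = (*x* − μ)/σ with μ, σ the mean and sample SD over days [−60, −30);
series with fewer than 5 baseline days or zero variance are unusable and
drop out of normalised analyses (mirroring the exclusion of losses lacking
pre-onset data). Rolling means (7-day for trajectory profiles, 3-day ahead
of the loss model) trail over *calendar* days with a minimum of one
observation, so gappy series keep their day set.

Population profiles report, per aligned day, the cross-pregnancy median,
interpolated 10–90 % quantiles, and a 95 % confidence interval of the
median from a seeded percentile bootstrap (B = 1000 by default). The
bootstrap was chosen because the upstream description names only a "95 %
CI" of the per-day median without a method; the percentile bootstrap makes
no distributional assumption and is exactly reproducible under a seed.
Days with fewer than three contributing pregnancies report the median
only.

Adjacent-trimester contrasts use the two-sided Mann-Whitney-Wilcoxon test
on per-pregnancy trimester means — exact when both samples are small and
tie-free, otherwise the tie-corrected normal approximation with continuity
correction — annotated on the conventional star ladder Bonferroni-corrected
for the 4 comparisons (\*: p ≤ 0.0125, \*\*: p ≤ 2.5e−3, \*\*\*:
p ≤ 2.5e−4, \*\*\*\*: p ≤ 2.5e−5). The advanced-maternal-age comparison
dichotomises the survey's 5-year age bins at 35 years and tests
per-time-bin means (1- or 4-week bins), Bonferroni-corrected across bins
within a series.

## Cumulative multimodal distance

The four most complete series (temperature peak, temperature trough, HR,
HRV, all z-scored) form a daily 4-vector; a day is usable only when all
four components are present. Each under-35 pregnancy is compared with the
leave-one-out mean of the other under-35 pregnancies; each 35-and-over
pregnancy with the full under-35 mean. Euclidean distances accumulate from
day −28 (4 weeks before DKP) through day 252 (40 weeks). Days failing the
completeness rule contribute zero and carry the cumulative value forward —
interpolation would fabricate data, and zero-contribution preserves
monotonicity. Endpoints are compared with the Kruskal-Wallis rank test
(the H statistic with tie correction; the package reports H even where the
statistic is sometimes informally labelled "U").

## The early-fetal-loss model

For each included loss, the nightly peak-temperature series (interior gaps
linearly interpolated, 3-day trailing mean, z-scored) contributes its 7
days following DPS (offsets 0–6), together with the *same calendar days*
from 5 full-term controls sampled without replacement per loss (reuse
across losses permitted — 22 usable losses × 5 = 110 control series drawn
from 97 full-term pregnancies forces reuse). Losses are grouped by
pregnancy length DPS − DKP using thresholds {14, 28, 40, 60} (smallest
threshold strictly greater than the length; the variant {14, 28, 40, 63}
is one argument away). Controls are sampled from the whole full-term pool,
screened for coverage of the matched window.

The model is a Gaussian GEE,
`z ~ Day * Category * LengthThreshold`, with the length threshold entering
as a numeric covariate (the reference analysis reports single coefficients
per term, not per-group dummies), each 7-day series as a cluster, and
Liang-Zeger robust standard errors. Category is coded 0 = loss,
1 = full-term, which makes the `Day` main effect the post-loss slope of
the losses and gives the published sign pattern a direct reading: `Day`
negative (losses decline), `Day:Category` positive (controls are flat),
`Day:Category:LengthThreshold` negative (the slope gap narrows for later
losses). The working correlation defaults to independence — for Gaussian
GEE with robust errors the coefficients are then exactly OLS, and with the
balanced 7-day clusters used here the exchangeable estimating equations
are solved by the same coefficients (a property the test suite asserts);
an iteratively estimated exchangeable structure is available via
`fit_gee(..., corstr = "exchangeable")`. No installed R package provides
GEE, so the estimator is implemented in the package and cross-checked in
the tests against `lm()` plus cluster-robust (sandwich) covariances.
Degenerate designs fail loudly: a single length group makes the threshold
collinear with the intercept and is rejected with advice to fit a reduced
formula.

## The synthetic cohort generator

`simulate_cohort()` draws survey rows, daily series and (optionally)
minute-level streams. Trajectories are piecewise linear with plateaus —
the simplest family reproducing every qualitative feature the analysis
targets:

* nightly peak temperature: a 28-day cycle (trough at each cycle start,
  the last trough on conception day −28; peak-to-trough amplitude 0.3 °C),
  a post-conception rise to 0.15 °C above the cycle peak, a plateau through
  pregnancy week 8, a decline to 0.1 °C below baseline at delivery, and
  postpartum recovery;
* nightly trough temperature: a 0.3 °C dip at onset then a steady rise of
  1.3 °C to delivery (the opposite trend to the peak);
* HR: a +3 bpm local peak 14 days after conception, a dip, then a slow
  rise peaking +8 bpm five weeks before delivery, returning to baseline
  postpartum; HRV mirrors it (−6 then −23 ms); RR and activity decline
  mildly (−0.5 rpm, −0.2 MET).

Baselines (36.3 / 31.0 °C, 67 bpm, 68 ms, 17.6 rpm, 2.2 MET), noise SDs
and between-subject SDs were set once to sit inside the trimester quantile
ranges a cohort of this kind exhibits; the reference study publishes no
effect sizes for trajectory amplitudes, so these are plausibility choices,
flagged as such here and in the configuration docs. Early fetal loss
replaces the trajectory from the loss day onward: nightly peak temperature
declines linearly at `0.03 − 3e−4 × loss_day` °C/day (clipped at
baseline), chosen so that against a ~0.12 °C baseline SD the z-scored
decline lands near the published coefficient scale, and so that the slope
shrinks with later losses — the minimal form that induces the published
three-way interaction sign. Other series relax exponentially to baseline
with a 14-day time constant. Loss days are drawn in [7, 59]: every
analysed loss must fall under the largest length threshold, so the
generator respects that by construction.

Minute-level streams (opt-in, for exercising the preprocessing stage) emit
temperature and MET at 1-minute cadence around the clock, HR/HRV at 5-min
and RR at 30-s cadence only inside each night's sleep interval, a 24-h
sinusoidal circadian component (nightly temperature maximum), duplicate
shorter sleep-summary rows to exercise longest-sleep selection, and
contiguous 30–240-min non-wear blocks with MET in [0, 0.5) and implausibly
cold temperature for the MET gate to remove.

**Fixture mode** reproduces the reference bookkeeping exactly: 52
partner-reported and 392 out-of-window survey rows; 224 delivered
pregnancies of which 47 carry an engineered sparse trimester (caught by
the 40 % filter), 76 an other-reason flag and 4 preterm gestations,
leaving 97 full-term; 34 losses of which 4 are failure-to-implant, 3 have
engineered sparse first trimesters and 4 carry a prior-completeness flag,
leaving 23 — one of which lacks all pre-onset data so that 22 enter the
z-scored loss analysis. Age bins and high-risk flags of the included
pregnancies follow the reference demographics table verbatim (49 under-35
vs 48 over-35 full-term pregnancies). Engineered sparse trimesters keep
20 % of days — far enough below the 40 % threshold that day-level
randomness cannot push a pregnancy across it.

What the simulator does **not** emulate: raw PPG waveforms or
accelerometer axes, timezone travel, device firmware changes, seasonal
temperature confounds, gestational complications other than EFL, or
correlated (non-independent) day-level missingness. Passing tests
therefore demonstrate that the *pipeline machinery* is correct and that
the analysis recovers the structure it assumes — not that real cohorts
satisfy those assumptions.

## Numerical choices and degenerate inputs

* Quantiles everywhere are type 7 (linear interpolation of order
  statistics), fixed for reproducibility.
* The MET gate uses strict inequality (a reading of exactly 0.5 MET is
  kept); quantile filtering retains values equal to either bound.
* Sleep intervals and the nightly window are half-open; a sample at 08:00
  belongs to the day, not the night.
* Mann-Whitney switches from the exact distribution to the tie-corrected
  normal approximation in the presence of ties or large samples; at
  n = 8 + 8 the two agree to ~0.01 in p.
* The Kruskal-Wallis chi-square p-value is a large-sample approximation;
  at 5 + 5 observations it tracks a permutation oracle closely in the
  rejection tail but can sit several hundredths above it mid-range — the
  test suite pins the tail behaviour, where decisions are made.
* Empty groups, empty trimesters, missing anchor dates, baselines without
  variance, losses without post-DPS days, and rank-deficient designs all
  produce explicit warnings, exclusions or errors rather than silent
  results.
* Seeds: every stochastic function takes a `seed` argument and derives
  independent child seeds internally; equal seeds give bitwise-identical
  output.

## Problem sizes

The shipped tests and the acceptance script run the fixture cohort
(702 survey rows, ~250 simulated pregnancies at daily resolution,
~540k daily values) in seconds-to-minutes on one core; minute-resolution
streams are generated only for a handful of pregnancy-days when the
preprocessing stage is exercised. Stochastic validation uses 10 reseeded
cohorts for signal recovery (50 pregnancies for the conception-rise test;
40 + 20 for the loss model) and 100 reseeded 16-pregnancy cohorts for the
type-I-error checks — sizes chosen so the whole suite stays comfortably
reproducible on a laptop while leaving the recovery criteria strict
(≥ 9/10, ≥ 8/10, ≤ 10 %).

## Known limitations

* The simulator's trajectory family is piecewise linear; real trajectories
  are smooth and heterogeneous in phase and amplitude.
* The length-threshold covariate is numeric, so the model assumes a linear
  threshold effect; with four thresholds this is an approximation the
  reference design also makes.
* `detect_cycle_trough()` is a diagnostic only — alignment always uses the
  survey dates, never re-anchors.
* Trimester-level inference treats pregnancies as exchangeable; the two
  participants contributing two pregnancies each are deliberately kept as
  independent units, a small amount of pseudoreplication accepted to keep
  resolution.
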