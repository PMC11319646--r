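#' Simulation configuration for synthetic pregnancy cohorts
#'
#' Collects every tunable of the synthetic-cohort generator with defaults
#' chosen to emulate the qualitative physiology of pregnancy as captured by a
#' finger-worn wearable: a ~28-day pre-conception distal-body-temperature
#' (DBT) cycle with a luteal rise, a conception rise past the cycle peak
#' followed by a slow decline across gestation, an opposite trend in the
#' nightly temperature trough, a heart-rate local peak about 14 days after
#' conception with a later gestational rise, mirrored heart-rate variability,
#' mild respiratory-rate and activity declines, postpartum recovery, and --
#' for early fetal loss (EFL) -- a post-loss temperature decline whose slope
#' shrinks with the day of loss.
#'
#' @param n_full_term,n_efl Number of full-term and EFL pregnancies drawn in
#'   free (non-fixture) simulation.
#' @param age_bins Data frame with columns `label` and `prob`: survey age
#'   bins and their sampling probabilities.
#' @param baseline Named numeric vector of population baselines per tracked
#'   series: `temp_peak` / `temp_trough` (deg C), `hr` (bpm), `hrv` (rmssd,
#'   ms), `rr` (rpm), `met` (dimensionless).
#' @param cycle_length_days Menstrual cycle length in days (>= 21).
#' @param luteal_amplitude Peak-to-trough amplitude of the pre-conception
#'   nightly-peak temperature cycle (deg C).
#' @param conception_rise Additional rise of the post-conception temperature
#'   plateau above the pre-conception cycle peak (deg C).
#' @param gestation_days_range Inclusive range for full-term gestation length
#'   in days, counted from conception (28 days before the day the pregnancy
#'   became known); full term requires >= 259 days (37 weeks).
#' @param efl_loss_day_range Inclusive range (days after the pregnancy became
#'   known) in which simulated EFL events occur; must sit inside the first
#'   trimester and under the largest pregnancy-length threshold of the loss
#'   analysis (60 days by default), as every analysed loss must belong to a
#'   length group.
#' @param efl_slope_intercept,efl_slope_per_day The post-loss nightly-peak
#'   temperature declines linearly at
#'   `efl_slope_intercept - efl_slope_per_day * loss_day` deg C per day
#'   (clipped at the pre-pregnancy baseline), so later losses decline more
#'   gently.
#' @param efl_relax_tau Time constant (days) of the exponential relaxation of
#'   the non-temperature-peak series back to baseline after a loss.
#' @param noise_sd Named numeric vector of day-level observation noise SDs
#'   per series (same names/units as `baseline`).
#' @param between_subject_sd Named numeric vector of between-pregnancy SDs of
#'   the constant subject offset per series.
#' @param missing_day_rate Probability that a given day's aggregates are
#'   absent for a pregnancy.
#' @param nonwear_rate Expected fraction of minute-level time spent in
#'   injected non-wear blocks (activity < 0.5 MET with implausible
#'   temperature).
#' @param end_drop Amount (deg C) by which nightly-peak temperature sits
#'   below baseline on the day of a full-term delivery.
#' @param trough_dip,trough_rise Early-pregnancy dip and at-delivery rise of
#'   the nightly trough temperature (deg C).
#'
#' @return A list of class `gw_sim_config`.
#' @export
sim_config <- function(n_full_term = 50,
                       n_efl = 10,
                       age_bins = default_age_bins(),
                       baseline = c(temp_peak = 36.3, temp_trough = 31,
                                    hr = 67, hrv = 68, rr = 17.6, met = 2.2),
                       cycle_length_days = 28,
                       luteal_amplitude = 0.3,
                       conception_rise = 0.15,
                       gestation_days_range = c(259, 287),
                       efl_loss_day_range = c(7, 59),
                       efl_slope_intercept = 0.03,
                       efl_slope_per_day = 3e-4,
                       efl_relax_tau = 14,
                       noise_sd = c(temp_peak = 0.1, temp_trough = 0.3,
                                    hr = 1.5, hrv = 5, rr = 0.5, met = 0.15),
                       between_subject_sd = c(temp_peak = 0.2,
                                              temp_trough = 1.8, hr = 7,
                                              hrv = 20, rr = 1.5, met = 0.4),
                       missing_day_rate = 0.1,
                       nonwear_rate = 0.05,
                       end_drop = 0.1,
                       trough_dip = 0.3,
                       trough_rise = 1.3) {
  cfg <- list(
    n_full_term = n_full_term, n_efl = n_efl,
    age_bins = tibble::as_tibble(age_bins),
    baseline = baseline,
    cycle_length_days = cycle_length_days,
    luteal_amplitude = luteal_amplitude,
    conception_rise = conception_rise,
    gestation_days_range = gestation_days_range,
    efl_loss_day_range = efl_loss_day_range,
    efl_slope_intercept = efl_slope_intercept,
    efl_slope_per_day = efl_slope_per_day,
    efl_relax_tau = efl_relax_tau,
    noise_sd = noise_sd,
    between_subject_sd = between_subject_sd,
    missing_day_rate = missing_day_rate,
    nonwear_rate = nonwear_rate,
    end_drop = end_drop,
    trough_dip = trough_dip,
    trough_rise = trough_rise
  )
  validate_sim_config(cfg)
  structure(cfg, class = "gw_sim_config")
}

validate_sim_config <- function(cfg) {
  gw_assert(cfg$missing_day_rate >= 0 && cfg$missing_day_rate <= 1,
            "`missing_day_rate` must lie in [0, 1]")
  gw_assert(cfg$nonwear_rate >= 0 && cfg$nonwear_rate <= 1,
            "`nonwear_rate` must lie in [0, 1]")
  gw_assert(cfg$cycle_length_days >= 21,
            "`cycle_length_days` must be >= 21")
  gw_assert(cfg$gestation_days_range[1] >= 259,
            "full-term gestation must be >= 259 days (37 weeks)")
  gw_assert(cfg$luteal_amplitude >= 0 && cfg$conception_rise >= 0,
            "amplitudes must be non-negative")
  series <- c("temp_peak", "temp_trough", "hr", "hrv", "rr", "met")
  gw_assert(all(series %in% names(cfg$baseline)),
            "`baseline` must name all six tracked series")
  gw_assert(all(series %in% names(cfg$noise_sd)) &&
              all(series %in% names(cfg$between_subject_sd)),
            "`noise_sd` and `between_subject_sd` must name all six series")
  gw_assert(all(abs(cfg$age_bins$prob) >= 0) &&
              abs(sum(cfg$age_bins$prob) - 1) < 1e-8,
            "`age_bins$prob` must be a probability vector")
  invisible(cfg)
}

#' @rdname sim_config
#' @export
default_age_bins <- function() {
  tibble::tibble(
    label = c("20-24", "25-29", "30-34", "35-39", "40-44", "45-49"),
    prob  = c(0.02, 0.12, 0.34, 0.34, 0.16, 0.02)
  )
}

#' Preprocessing configuration
#'
#' Thresholds of the raw-sample cleaning pipeline: two quantile-filter
#' passes, the activity (MET) non-wear gate, the fixed nightly clock window,
#' and the quantile bands defining the daily "peak" and "trough" statistics.
#'
#' @param first_pass_quantiles,second_pass_quantiles Lower/upper quantile
#'   bounds of the two filtering passes.
#' @param met_gate Samples whose nearest-in-time activity reading is strictly
#'   below this MET value are treated as non-wear and dropped.
#' @param met_pair_tolerance_s Maximum |time difference| (seconds) for an
#'   activity reading to count as corresponding to a sample.
#' @param nightly_start,nightly_end Local clock hours bounding the nightly
#'   window `[nightly_start, nightly_end)` (spanning midnight).
#' @param peak_band,trough_band Midpoint-rank bands whose sample values are
#'   averaged into the daily peak and trough.
#' @param peak_definition `"band_mean"` (mean of the order statistics inside
#'   the band, the default) or `"endpoint_mean"` (mean of the two interpolated
#'   band-endpoint quantiles).
#'
#' @return A list of class `gw_preprocess_config`.
#' @export
preprocess_config <- function(first_pass_quantiles = c(0.05, 0.95),
                              second_pass_quantiles = c(0.02, 0.98),
                              met_gate = 0.5,
                              met_pair_tolerance_s = 60,
                              nightly_start = 20,
                              nightly_end = 8,
                              peak_band = c(0.90, 0.95),
                              trough_band = c(0.05, 0.10),
                              peak_definition = c("band_mean",
                                                  "endpoint_mean")) {
  for (q in list(first_pass_quantiles, second_pass_quantiles,
                 peak_band, trough_band)) {
    gw_assert(length(q) == 2 && q[1] >= 0 && q[1] < q[2] && q[2] <= 1,
              "quantile pairs must satisfy 0 <= low < high <= 1")
  }
  structure(
    list(first_pass_quantiles = first_pass_quantiles,
         second_pass_quantiles = second_pass_quantiles,
         met_gate = met_gate,
         met_pair_tolerance_s = met_pair_tolerance_s,
         nightly_start = nightly_start,
         nightly_end = nightly_end,
         peak_band = peak_band,
         trough_band = trough_band,
         peak_definition = match.arg(peak_definition)),
    class = "gw_preprocess_config"
  )
}

#' Pregnancy alignment scheme
#'
#' Day-0 is the anchor date (the day the pregnancy became known, DKP, for
#' trajectory analyses; the day the pregnancy stopped, DPS, for peridelivery
#' and loss analyses).  Trimester windows are half-open day intervals that
#' partition `[-91, 343)`; conception is modelled 28 days before DKP, so the
#' first trimester starts at day -28.  The pre-pregnancy baseline window used
#' for z-scoring is `[-60, -30)` relative to DKP.
#'
#' @param baseline_window Half-open day interval (relative to DKP) over which
#'   each pregnancy's baseline mean/SD is computed.
#'
#' @return A list of class `gw_alignment_scheme` with elements
#'   `trimester_windows` (tibble: trimester, start, end) and
#'   `baseline_window`.
#' @export
alignment_scheme <- function(baseline_window = c(-60, -30)) {
  windows <- tibble::tibble(
    trimester = c("t-1", "t1", "t2", "t3", "t4"),
    start = c(-91L, -28L, 63L, 154L, 252L),
    end   = c(-28L, 63L, 154L, 252L, 343L)
  )
  gw_assert(all(windows$end[-5] == windows$start[-1]),
            "trimester windows must be contiguous")
  gw_assert(baseline_window[1] < baseline_window[2] &&
              baseline_window[2] <= windows$start[2],
            "baseline window must precede the first trimester")
  structure(list(trimester_windows = windows,
                 baseline_window = baseline_window),
            class = "gw_alignment_scheme")
}

# The six tracked daily series and their (modality, statistic, window)
# identity in aggregate tables.
gw_series_map <- function() {
  tibble::tibble(
    series    = c("temp_peak", "temp_trough", "hr", "hrv", "rr", "met"),
    modality  = c("temperature", "temperature", "hr", "hrv", "rr", "met"),
    statistic = c("peak", "trough", "peak", "peak", "peak", "peak"),
    window    = c("nightly", "nightly", "nightly", "nightly", "nightly", "h24")
  )
}
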