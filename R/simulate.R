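#' Simulate daily physiological series for one pregnancy
#'
#' Generates the six tracked daily series (nightly peak and trough distal
#' body temperature, nightly peak heart rate, heart-rate variability and
#' respiratory rate, 24-h peak activity) for a single pregnancy from day -91
#' relative to the day the pregnancy became known (DKP, day 0) through 91
#' days after the day the pregnancy stopped (DPS).  Conception is modelled at
#' day -28.
#'
#' The noiseless trajectories are piecewise linear with plateaus:
#' * nightly peak temperature cycles before conception (trough at each cycle
#'   start, the last one on conception day -28), rises past the cycle peak to
#'   a plateau held through pregnancy week 8, then declines below the
#'   pre-pregnancy baseline at delivery and recovers postpartum;
#' * nightly trough temperature dips at onset then rises steadily until
#'   delivery;
#' * heart rate peaks locally 14 days after conception, dips, then climbs to
#'   a maximum a few weeks before delivery and returns to baseline
#'   postpartum; heart-rate variability mirrors it;
#' * respiratory rate and activity decline mildly and recover postpartum.
#'
#' A constant per-pregnancy offset (SD `config$between_subject_sd`) and
#' day-level Gaussian noise (SD `config$noise_sd`) are added on top.
#' Identical `(spec, config, seed)` give bitwise-identical output.
#'
#' @param spec A one-row data frame (or list) with at least `pregnancy_id`,
#'   `dkp` and `dps` (Dates, `dps > dkp`).
#' @param config A [sim_config()].
#' @param seed Integer seed.
#'
#' @return A tibble with columns `day`, `series`, `value` and attribute
#'   `"truth"` (list: per-series subject offsets and the noiseless
#'   trajectory parameters).
#' @export
simulate_pregnancy_series <- function(spec, config = sim_config(), seed = 1) {
  core <- gw_simulate_core(spec, config, seed)
  noisy <- gw_add_noise(core$truth, config, core$noise_seed)
  attr(noisy, "truth") <- core[c("offsets", "params")]
  noisy
}

# Noiseless trajectory (subject offset included) plus bookkeeping.
gw_simulate_core <- function(spec, config, seed) {
  spec <- as.list(spec)
  gw_assert(!is.null(spec$dkp) && !is.na(spec$dkp),
            "pregnancy spec field `dkp` is missing")
  gw_assert(!is.null(spec$dps) && !is.na(spec$dps),
            "pregnancy spec field `dps` is missing")
  dps_offset <- as.integer(as.Date(spec$dps) - as.Date(spec$dkp))
  if (dps_offset <= 0) {
    rlang::abort("pregnancy spec field `dps` must postdate `dkp`")
  }
  seeds <- gw_child_seeds(seed, 2)
  series <- gw_series_map()$series
  offsets <- withr::with_seed(seeds[1], {
    stats::setNames(stats::rnorm(length(series), 0,
                                 config$between_subject_sd[series]), series)
  })
  days <- seq(-91L, dps_offset + 91L)
  params <- list(conception = -28L, dps_offset = dps_offset,
                 # EFL specs stop early: the pre-loss envelope follows a
                 # nominal full-term course, truncated by inject_efl().
                 e_traj = if (dps_offset >= 180L) dps_offset else 245L)
  truth <- purrr::map(series, function(s) {
    tibble::tibble(day = days, series = s,
                   value = gw_truth_value(days, s, config, params) +
                     offsets[[s]])
  }) %>% dplyr::bind_rows()
  list(truth = truth, offsets = offsets, params = params,
       noise_seed = seeds[2])
}

gw_add_noise <- function(truth, config, seed) {
  withr::with_seed(seed, {
    truth %>%
      dplyr::group_by(.data$series) %>%
      dplyr::mutate(value = .data$value +
                      stats::rnorm(dplyr::n(), 0,
                                   config$noise_sd[[.data$series[1]]])) %>%
      dplyr::ungroup()
  })
}

# Noiseless population-level trajectory value for one series.
gw_truth_value <- function(day, series, config, params) {
  b <- config$baseline[[series]]
  C <- params$conception
  E <- params$e_traj
  switch(series,
    temp_peak = {
      L <- config$cycle_length_days
      amp <- config$luteal_amplitude
      hi <- b + amp + config$conception_rise
      phase <- (day - C) %% L
      cyc <- b + amp * pmin(phase / (L / 2), 1, (L - phase) / 4)
      post <- gw_piecewise(day, c(C, C + 14, 56, E, E + 42, E + 91),
                           c(b, hi, hi, b - config$end_drop, b, b))
      ifelse(day < C, cyc, post)
    },
    temp_trough = gw_piecewise(
      day, c(-91, C, C + 21, E, E + 60, E + 91),
      c(b, b, b - config$trough_dip, b + config$trough_rise,
        b + 0.4, b + 0.2)),
    hr = gw_piecewise(
      day, c(-91, C, C + 14, C + 28, E - 35, E, E + 21, E + 91),
      c(b, b, b + 3, b + 0.5, b + 8, b + 6, b, b)),
    hrv = gw_piecewise(
      day, c(-91, C, C + 14, C + 28, E - 35, E, E + 21, E + 91),
      c(b, b, b - 6, b - 1, b - 23, b - 18, b + 5, b)),
    rr = gw_piecewise(
      day, c(-91, C, E, E + 60, E + 91),
      c(b, b, b - 0.5, b - 0.2, b - 0.2)),
    met = gw_piecewise(
      day, c(-91, C, E, E + 14, E + 91),
      c(b, b, b - 0.2, b - 0.1, b)),
    rlang::abort(paste0("unknown series `", series, "`"))
  )
}

#' Inject an early-fetal-loss signature into a daily series
#'
#' From `loss_day` (days after DKP) onward the nightly-peak temperature
#' declines linearly toward the pre-pregnancy baseline at
#' `config$efl_slope_intercept - config$efl_slope_per_day * loss_day`
#' deg C per day (clipped at baseline), so losses later in the first
#' trimester decline more gently.  Every other series relaxes exponentially
#' back to its baseline with time constant `config$efl_relax_tau` days.
#'
#' Apply to a noiseless series (observation noise is added afterwards by the
#' cohort generator).
#'
#' @param series A daily series tibble (`day`, `series`, `value`).
#' @param loss_day Integer day of loss, strictly inside the first trimester
#'   (0 < loss_day < 91).
#' @param config A [sim_config()].
#' @param baseline Named per-series baselines to relax toward; defaults to
#'   `config$baseline` (pass baseline + subject offset for subject-level
#'   realism).
#'
#' @return The modified series tibble.
#' @export
inject_efl <- function(series, loss_day, config = sim_config(),
                       baseline = config$baseline) {
  if (!(loss_day > 0 && loss_day < 91)) {
    rlang::abort("`loss_day` must lie strictly inside the first trimester (0, 91)")
  }
  slope <- config$efl_slope_intercept - config$efl_slope_per_day * loss_day
  tau <- config$efl_relax_tau
  series %>%
    dplyr::group_by(.data$series) %>%
    dplyr::group_modify(function(df, key) {
      s <- key$series[[1]]
      b <- baseline[[s]]
      post <- df$day >= loss_day
      if (any(post)) {
        v0 <- df$value[df$day == loss_day]
        if (length(v0) == 0) v0 <- df$value[which(post)[1]]
        k <- df$day[post] - loss_day
        df$value[post] <- if (s == "temp_peak") {
          pmax(b, v0 - slope * k)
        } else {
          b + (v0 - b) * exp(-k / tau)
        }
      }
      df
    }) %>%
    dplyr::ungroup() %>%
    dplyr::select(dplyr::all_of(names(series)))
}

#' Expand daily series into minute-level sample streams
#'
#' Emits raw sensor-sample rows at the device cadences: temperature and
#' activity (MET) at 1-minute intervals around the clock; heart rate and
#' heart-rate variability at 5-minute and respiratory rate at 30-second
#' intervals only inside each night's sleep interval.  Each sample is the
#' day's value plus a 24-h circadian component and noise.  Contiguous
#' non-wear blocks (30-240 min) are injected at an expected time fraction
#' `config$nonwear_rate`, with activity drawn in `[0, 0.5)` and
#' physiologically implausible temperature.  One sleep-summary row is emitted
#' per night, with occasional duplicate shorter rows to exercise
#' longest-sleep selection.
#'
#' @param daily Daily series tibble (`day`, `series`, `value`) for one
#'   pregnancy.
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @param dkp Date mapped to `day == 0`.
#' @param participant_id,pregnancy_id Identifiers stamped on the output.
#'
#' @return A list with `samples` (participant_id, pregnancy_id,
#'   timestamp_local, modality, value) and `sleep` (participant_id, date,
#'   sleep_start, sleep_end, duration_s).
#' @export
simulate_minute_stream <- function(daily, config = sim_config(), seed = 1,
                                   dkp = as.Date("2021-01-01"),
                                   participant_id = "p001",
                                   pregnancy_id = "g001") {
  days <- sort(unique(daily$day))
  if (length(days) == 0L) {
    return(list(
      samples = tibble::tibble(participant_id = character(),
                               pregnancy_id = character(),
                               timestamp_local = as.POSIXct(character(),
                                                            tz = "UTC"),
                               modality = character(), value = double()),
      sleep = tibble::tibble(participant_id = character(),
                             date = as.Date(character()),
                             sleep_start = as.POSIXct(character(), tz = "UTC"),
                             sleep_end = as.POSIXct(character(), tz = "UTC"),
                             duration_s = double())
    ))
  }
  wide <- daily %>%
    tidyr::pivot_wider(names_from = "series", values_from = "value")
  withr::with_seed(seed, {
    per_day <- purrr::map(seq_len(nrow(wide)), function(i) {
      row <- wide[i, ]
      d0 <- as.POSIXct(dkp, tz = "UTC") + row$day * 86400
      date <- dkp + row$day

      # sleep interval for the night starting on `date`
      start <- d0 + 23 * 3600 + stats::runif(1, 0, 3600)
      dur <- stats::runif(1, 7, 8.5) * 3600
      sleep <- tibble::tibble(participant_id = participant_id,
                              date = date, sleep_start = start,
                              sleep_end = start + dur, duration_s = dur)
      if (stats::runif(1) < 0.2) {  # duplicate, shorter candidate row
        sleep <- dplyr::bind_rows(
          sleep,
          tibble::tibble(participant_id = participant_id, date = date,
                         sleep_start = start + 1800,
                         sleep_end = start + dur * 0.6,
                         duration_s = dur * 0.6 - 1800))
      }

      mins <- d0 + seq(0, 1439) * 60
      hour <- (as.numeric(mins - d0) / 3600)
      night_shape <- (1 + cos(2 * pi * (hour - 3) / 24)) / 2
      temp <- row$temp_trough +
        (row$temp_peak - row$temp_trough) * night_shape +
        stats::rnorm(1440, 0, 0.05)
      in_sleep <- mins >= start & mins < start + dur
      met <- ifelse(in_sleep,
                    pmax(0.6, 0.9 + stats::rnorm(1440, 0, 0.05)),
                    1.2 + abs(stats::rnorm(1440, 0, 0.5)))

      # contiguous non-wear blocks (noise-free MET strictly < 0.5)
      if (config$nonwear_rate > 0) {
        n_blocks <- stats::rpois(1, config$nonwear_rate * 1440 / 135)
        for (b in seq_len(n_blocks)) {
          len <- round(stats::runif(1, 30, 240))
          at <- sample.int(1440 - len, 1)
          idx <- at:(at + len - 1)
          met[idx] <- stats::runif(len, 0, 0.49)
          temp[idx] <- 30 + stats::rnorm(len, 0, 0.2)
        }
      }

      samples <- dplyr::bind_rows(
        tibble::tibble(timestamp_local = mins, modality = "temperature",
                       value = temp),
        tibble::tibble(timestamp_local = mins, modality = "met", value = met)
      )
      ppg_t <- mins[in_sleep]
      if (length(ppg_t) > 0) {
        five <- ppg_t[seq(1, length(ppg_t), by = 5)]
        samples <- dplyr::bind_rows(
          samples,
          tibble::tibble(timestamp_local = five, modality = "hr",
                         value = row$hr + stats::rnorm(length(five), 0, 2)),
          tibble::tibble(timestamp_local = five, modality = "hrv",
                         value = row$hrv + stats::rnorm(length(five), 0, 5)),
          {
            thirty <- rep(ppg_t, each = 2) + c(0, 30)
            thirty <- thirty[thirty < start + dur]
            tibble::tibble(timestamp_local = thirty, modality = "rr",
                           value = row$rr +
                             stats::rnorm(length(thirty), 0, 0.5))
          }
        )
      }
      list(samples = samples, sleep = sleep)
    })
    samples <- purrr::map(per_day, "samples") %>% dplyr::bind_rows() %>%
      dplyr::mutate(participant_id = participant_id,
                    pregnancy_id = pregnancy_id, .before = 1)
    sleep <- purrr::map(per_day, "sleep") %>% dplyr::bind_rows()
    list(samples = samples, sleep = sleep)
  })
}

#' Simulate a full synthetic cohort
#'
#' Draws pregnancy specs (survey rows), daily trajectories and -- optionally
#' for a subset -- minute-level raw streams.  In fixture mode the survey
#' bookkeeping reproduces the reference study design exactly: 52
#' partner-reported and 392 out-of-window pregnancies (survey rows only); 224
#' delivered-in-window pregnancies of which 47 have an engineered sparse
#' trimester, 76 carry an other-reason sparse flag and 4 are preterm, leaving
#' 97 full-term; 34 reported early fetal losses of which 4 are
#' failure-to-implant, 3 have engineered low first-trimester completeness and
#' 4 carry a low prior-completeness flag, leaving 23 -- one of which lacks
#' all pre-onset data so that 22 are usable for baseline z-scoring.  Age-bin
#' and high-risk counts of the included pregnancies follow the reference
#' demographics table.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; equal seeds give identical cohorts.
#' @param fixture If `TRUE`, generate the fixed bookkeeping cohort above
#'   (ignoring `n_full_term` / `n_efl`).
#' @param minute_ids Character vector of pregnancy ids for which minute-level
#'   streams are also generated (default none; daily resolution is the
#'   default for speed).
#'
#' @return A list of class `gw_cohort_sim` with elements `survey`, `daily`
#'   (long daily aggregates: participant_id, pregnancy_id, date, window,
#'   modality, statistic, value), `truth`, and (when requested) `samples` and
#'   `sleep`.
#' @export
simulate_cohort <- function(config = sim_config(), seed = 1,
                            fixture = FALSE, minute_ids = NULL) {
  survey <- if (fixture) gw_fixture_survey(config, seed)
            else gw_free_survey(config, seed)
  with_data <- survey %>%
    dplyr::filter(!.data$outcome %in% c("partner_report", "out_of_window"))
  seeds <- gw_child_seeds(seed + 1L, nrow(with_data) + 1L)
  sims <- purrr::map(seq_len(nrow(with_data)), function(i) {
    gw_simulate_daily_one(with_data[i, ], config, seeds[i])
  })
  daily <- dplyr::bind_rows(purrr::map(sims, "daily"))
  truth <- dplyr::bind_rows(purrr::map(sims, "truth"))
  out <- list(survey = survey, daily = daily, truth = truth,
              config = config, seed = seed, fixture = fixture)
  if (length(minute_ids) > 0) {
    mseed <- gw_child_seeds(seed + 2L, length(minute_ids))
    streams <- purrr::map(seq_along(minute_ids), function(j) {
      id <- minute_ids[j]
      row <- survey[survey$pregnancy_id == id, ]
      gw_assert(nrow(row) == 1, paste0("unknown pregnancy id `", id, "`"))
      day_vals <- daily %>%
        dplyr::filter(.data$pregnancy_id == id) %>%
        dplyr::inner_join(gw_series_map(),
                          by = c("modality", "statistic", "window")) %>%
        dplyr::mutate(day = as.integer(.data$date - row$dkp)) %>%
        dplyr::select("day", "series", "value")
      simulate_minute_stream(day_vals, config, mseed[j], dkp = row$dkp,
                             participant_id = row$participant_id,
                             pregnancy_id = id)
    })
    out$samples <- dplyr::bind_rows(purrr::map(streams, "samples"))
    out$sleep <- dplyr::bind_rows(purrr::map(streams, "sleep"))
  }
  structure(out, class = "gw_cohort_sim")
}

# One pregnancy: daily long-format aggregates + truth row.
gw_simulate_daily_one <- function(spec, config, seed) {
  core <- gw_simulate_core(spec, config, seed)
  truth_series <- core$truth
  loss_day <- NA_integer_
  slope <- NA_real_
  if (startsWith(spec$outcome, "efl")) {
    loss_day <- core$params$dps_offset
    slope <- config$efl_slope_intercept - config$efl_slope_per_day * loss_day
    truth_series <- inject_efl(
      truth_series, loss_day, config,
      baseline = config$baseline[names(core$offsets)] + core$offsets)
  }
  noisy <- gw_add_noise(truth_series, config, core$noise_seed)

  keep_days <- gw_observed_days(spec, core$params$dps_offset, config,
                                seed + 7L)
  daily <- noisy %>%
    dplyr::filter(.data$day %in% keep_days) %>%
    dplyr::inner_join(gw_series_map(), by = "series") %>%
    dplyr::mutate(participant_id = spec$participant_id,
                  pregnancy_id = spec$pregnancy_id,
                  date = spec$dkp + .data$day) %>%
    dplyr::select("participant_id", "pregnancy_id", "date",
                  "window", "modality", "statistic", "value")
  truth <- tibble::tibble(
    pregnancy_id = spec$pregnancy_id, outcome = spec$outcome,
    dps_offset = core$params$dps_offset, loss_day = loss_day,
    post_loss_slope = slope, offsets = list(core$offsets)
  )
  list(daily = daily, truth = truth)
}

# Day-level missingness plus the engineered sparsity patterns used by
# fixture mode (sparsity_pattern column: "", "sparse_t2", "sparse_t1",
# "no_preonset").
gw_observed_days <- function(spec, dps_offset, config, seed) {
  days <- seq(-91L, dps_offset + 91L)
  withr::with_seed(seed, {
    keep <- stats::runif(length(days)) >= config$missing_day_rate
    pat <- if ("sparsity_pattern" %in% names(spec)) spec$sparsity_pattern else ""
    if (identical(pat, "sparse_t2")) {
      in_t2 <- days >= 63L & days < 154L
      keep[in_t2] <- stats::runif(sum(in_t2)) < 0.20
    } else if (identical(pat, "sparse_t1")) {
      in_t1 <- days >= -28L & days < 63L
      keep[in_t1] <- stats::runif(sum(in_t1)) < 0.20
    } else if (identical(pat, "no_preonset")) {
      keep[days < -28L] <- FALSE
    }
    days[keep]
  })
}

# Free-mode survey: n_full_term + n_efl pregnancies, one per participant.
gw_free_survey <- function(config, seed) {
  n <- config$n_full_term + config$n_efl
  withr::with_seed(seed, {
    ids <- sprintf("g%04d", seq_len(n))
    dkp <- as.Date("2020-06-01") + sample.int(365, n, replace = TRUE)
    is_efl <- rep(c(FALSE, TRUE), c(config$n_full_term, config$n_efl))
    dps_off <- integer(n)
    dps_off[!is_efl] <- sample(
      seq(config$gestation_days_range[1] - 28L,
          config$gestation_days_range[2] - 28L),
      sum(!is_efl), replace = TRUE)
    if (any(is_efl)) {
      dps_off[is_efl] <- sample(
        seq(config$efl_loss_day_range[1], config$efl_loss_day_range[2]),
        sum(is_efl), replace = TRUE)
    }
    subtype <- sample(c("efl_miscarriage", "efl_ectopic", "efl_chemical",
                        "efl_termination"),
                      n, replace = TRUE,
                      prob = c(0.6, 0.1, 0.2, 0.1))
    tibble::tibble(
      participant_id = sprintf("p%04d", seq_len(n)),
      pregnancy_id = ids,
      age_bin = sample(config$age_bins$label, n, replace = TRUE,
                       prob = config$age_bins$prob),
      dkp = dkp,
      dps = dkp + dps_off,
      outcome = ifelse(is_efl, subtype, "delivered"),
      high_risk = stats::runif(n) < 0.15,
      sparsity_pattern = "",
      sparse_flag = "none"
    )
  })
}

# Reference-study demographics for included pregnancies
# (columns: full-term all / high-risk, EFL all / high-risk).
gw_fixture_demographics <- function() {
  tibble::tibble(
    age_bin = c("25-29", "30-34", "35-39", "40-44", "45-49"),
    ft_all  = c(13L, 36L, 29L, 17L, 2L),
    ft_hr   = c(2L, 2L, 4L, 7L, 2L),
    efl_all = c(1L, 5L, 14L, 3L, 0L),
    efl_hr  = c(0L, 0L, 5L, 2L, 0L)
  )
}

gw_fixture_survey <- function(config, seed) {
  demo <- gw_fixture_demographics()
  withr::with_seed(seed, {
    rand_bins <- function(n) sample(config$age_bins$label, n, replace = TRUE,
                                    prob = config$age_bins$prob)
    mk <- function(n, prefix) sprintf("%s%04d", prefix, seq_len(n))

    # --- delivered-in-window arm: 97 clean + 47 sparse + 76 flagged + 4 preterm
    n_del <- 224L
    del_pattern <- c(rep("", 97L), rep("sparse_t2", 47L), rep("", 76L + 4L))
    del_flag <- c(rep("none", 97L + 47L), rep("sparse_other", 76L),
                  rep("none", 4L))
    del_gest <- c(sample(seq(231L, 259L), 97L + 47L + 76L, replace = TRUE),
                  sample(seq(170L, 215L), 4L, replace = TRUE))
    ft_bins <- rep(demo$age_bin, demo$ft_all)
    ft_risk <- unlist(purrr::map2(demo$ft_hr, demo$ft_all,
                                  ~ rep(c(TRUE, FALSE), c(.x, .y - .x))))
    del_age <- c(ft_bins, rand_bins(n_del - 97L))
    del_high <- c(ft_risk, stats::runif(n_del - 97L) < 0.15)
    # 97 pregnancies from 96 individuals: the last clean pregnancy shares a
    # participant with the first.
    del_pid <- mk(n_del, "pd")
    del_pid[97L] <- del_pid[1L]
    delivered <- tibble::tibble(
      participant_id = del_pid,
      pregnancy_id = mk(n_del, "gd"),
      age_bin = del_age,
      dkp = as.Date("2020-03-01") + sample.int(400, n_del, replace = TRUE),
      outcome = "delivered", high_risk = del_high,
      sparsity_pattern = del_pattern, sparse_flag = del_flag
    ) %>% dplyr::mutate(dps = .data$dkp + del_gest, .after = "dkp")

    # --- EFL arm: 23 clean (1 without pre-onset data) + 3 sparse-t1 +
    #     4 flagged + 4 failure-to-implant
    n_efl <- 34L
    efl_pattern <- c("no_preonset", rep("", 22L), rep("sparse_t1", 3L),
                     rep("", 8L))
    efl_flag <- c(rep("none", 23L + 3L), rep("low_prior_completeness", 4L),
                  rep("none", 4L))
    efl_outcome <- c(sample(c("efl_miscarriage", "efl_ectopic",
                              "efl_chemical", "efl_termination"),
                            30L, replace = TRUE, prob = c(0.6, 0.1, 0.2, 0.1)),
                     rep("efl_failure_to_implant", 4L))
    efl_bins <- rep(demo$age_bin, demo$efl_all)
    efl_risk <- unlist(purrr::map2(demo$efl_hr, demo$efl_all,
                                   ~ rep(c(TRUE, FALSE), c(.x, .y - .x))))
    efl_age <- c(efl_bins, rand_bins(n_efl - 23L))
    efl_high <- c(efl_risk, stats::runif(n_efl - 23L) < 0.2)
    # 23 included pregnancies from 20 individuals: three participants carry
    # two pregnancies each.
    efl_pid <- mk(n_efl, "pe")
    efl_pid[21L:23L] <- efl_pid[1L:3L]
    loss <- sample(seq(config$efl_loss_day_range[1],
                       config$efl_loss_day_range[2]),
                   n_efl, replace = TRUE)
    efl <- tibble::tibble(
      participant_id = efl_pid,
      pregnancy_id = mk(n_efl, "ge"),
      age_bin = efl_age,
      dkp = as.Date("2020-03-01") + sample.int(400, n_efl, replace = TRUE),
      outcome = efl_outcome, high_risk = efl_high,
      sparsity_pattern = efl_pattern, sparse_flag = efl_flag
    ) %>% dplyr::mutate(dps = .data$dkp + loss, .after = "dkp")

    # --- survey-only rows
    partner <- tibble::tibble(
      participant_id = mk(52L, "pp"), pregnancy_id = mk(52L, "gp"),
      age_bin = rand_bins(52L),
      dkp = as.Date("2020-03-01") + sample.int(400, 52L, replace = TRUE),
      outcome = "partner_report", high_risk = FALSE,
      sparsity_pattern = "", sparse_flag = "none"
    ) %>% dplyr::mutate(dps = .data$dkp + 250L, .after = "dkp")
    outwin <- tibble::tibble(
      participant_id = mk(392L, "po"), pregnancy_id = mk(392L, "go"),
      age_bin = rand_bins(392L),
      dkp = as.Date("2015-01-01") + sample.int(1200, 392L, replace = TRUE),
      outcome = "out_of_window", high_risk = FALSE,
      sparsity_pattern = "", sparse_flag = "none"
    ) %>% dplyr::mutate(dps = .data$dkp + 250L, .after = "dkp")

    dplyr::bind_rows(delivered, efl, partner, outwin)
  })
}
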