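#' Read and normalise raw sensor-sample tables
#'
#' Reads one or more long-format sample tables (CSV, or Parquet when the
#' `arrow` package is available), coerces timestamps to naive local
#' datetimes, drops rows whose timestamp cannot be parsed (erroring when more
#' than 10\% of rows are rejected), collapses exact duplicate
#' (participant, modality, timestamp) rows keeping the first, and sorts by
#' participant then time.
#'
#' @param paths Character vector of file paths, or a data frame already in
#'   memory (columns `participant_id`, `pregnancy_id`, `timestamp_local`,
#'   `modality`, `value`).
#'
#' @return A sample tibble sorted by participant and time.
#' @export
load_and_normalize <- function(paths) {
  raw <- if (is.data.frame(paths)) {
    tibble::as_tibble(paths)
  } else {
    purrr::map(paths, function(p) {
      if (grepl("\\.parquet$", p)) {
        rlang::check_installed("arrow", "to read Parquet sample files")
        tibble::as_tibble(arrow::read_parquet(p))
      } else {
        readr::read_csv(p, show_col_types = FALSE,
                        col_types = readr::cols(
                          timestamp_local = readr::col_character(),
                          .default = readr::col_guess()))
      }
    }) %>% dplyr::bind_rows()
  }
  ts <- raw$timestamp_local
  if (!inherits(ts, "POSIXct")) {
    x <- as.character(ts)
    ts <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01",
                     tz = "UTC")
    for (fmt in c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                  "%Y-%m-%d %H:%M", "%Y-%m-%d")) {
      miss <- is.na(ts)
      if (!any(miss)) break
      ts[miss] <- as.POSIXct(strptime(x[miss], fmt, tz = "UTC"))
    }
  }
  bad <- is.na(ts) | !is.finite(raw$value)
  if (any(bad)) {
    if (mean(bad) > 0.10) {
      rlang::abort(sprintf(
        "%.1f%% of rows rejected (unparseable timestamp or non-finite value)",
        100 * mean(bad)))
    }
    rlang::inform(sprintf("dropped %d unparseable/non-finite rows", sum(bad)))
  }
  raw %>%
    dplyr::mutate(timestamp_local = ts,
                  modality = tolower(.data$modality)) %>%
    dplyr::filter(!bad) %>%
    dplyr::distinct(.data$participant_id, .data$modality,
                    .data$timestamp_local, .keep_all = TRUE) %>%
    dplyr::arrange(.data$participant_id, .data$timestamp_local)
}

#' Select the longest sleep record per participant-night
#'
#' Keeps exactly one row per (participant, date): the one with the largest
#' `duration_s`, ties broken by the earliest `sleep_start`.
#'
#' @param sleep Sleep-summary tibble (`participant_id`, `date`,
#'   `sleep_start`, `sleep_end`, `duration_s`).
#' @return The filtered tibble.
#' @export
select_longest_sleep <- function(sleep) {
  sleep %>%
    dplyr::group_by(.data$participant_id, .data$date) %>%
    dplyr::arrange(dplyr::desc(.data$duration_s), .data$sleep_start,
                   .by_group = TRUE) %>%
    dplyr::slice_head(n = 1) %>%
    dplyr::ungroup()
}

#' Quantile-band filter of raw samples
#'
#' Within each scope group, drops values strictly below the interpolated
#' `low` quantile or strictly above the `high` quantile (order-statistic
#' interpolation, R type 7).  Because the streams carry different physical
#' units, quantiles are always computed within a modality; the scope chooses
#' whether a participant's samples are additionally pooled across
#' pregnancies (`per_participant`) or split by pregnancy
#' (`per_participant_modality`).
#'
#' @param samples Sample tibble.
#' @param low,high Quantile bounds, `0 <= low < high <= 1`.
#' @param scope Grouping scope (see above).
#' @return The filtered sample tibble.
#' @export
quantile_filter <- function(samples, low, high,
                            scope = c("per_participant",
                                      "per_participant_modality")) {
  scope <- match.arg(scope)
  gw_assert(low >= 0 && low < high && high <= 1,
            "quantile bounds must satisfy 0 <= low < high <= 1")
  if (nrow(samples) == 0) {
    rlang::warn("quantile_filter: empty input passes through")
    return(samples)
  }
  groups <- c("participant_id", "modality")
  if (scope == "per_participant_modality" &&
      "pregnancy_id" %in% names(samples)) {
    groups <- c("participant_id", "pregnancy_id", "modality")
  }
  samples %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(groups))) %>%
    dplyr::filter(.data$value >= gw_quantile(.data$value, low),
                  .data$value <= gw_quantile(.data$value, high)) %>%
    dplyr::ungroup()
}

#' Drop samples whose corresponding activity reading indicates non-wear
#'
#' A non-activity sample is dropped iff the nearest-in-time MET sample from
#' the same participant within `tolerance_s` seconds has a value strictly
#' below `met_gate`.  MET samples themselves are never dropped, and samples
#' with no MET reading within the tolerance are retained.
#'
#' @param samples Sample tibble.
#' @param met_gate MET threshold (strict inequality).
#' @param tolerance_s Pairing tolerance in seconds.
#' @return The filtered sample tibble.
#' @export
met_gate_filter <- function(samples, met_gate = 0.5, tolerance_s = 60) {
  samples %>%
    dplyr::group_by(.data$participant_id) %>%
    dplyr::group_modify(function(df, key) {
      met <- df %>% dplyr::filter(.data$modality == "met") %>%
        dplyr::arrange(.data$timestamp_local)
      if (nrow(met) == 0) {
        rlang::warn(paste0("no MET stream for participant `",
                           key$participant_id, "`; gate not applied"))
        return(df)
      }
      is_met <- df$modality == "met"
      t <- as.numeric(df$timestamp_local)
      mt <- as.numeric(met$timestamp_local)
      idx <- findInterval(t, mt)
      lo <- pmax(idx, 1L)
      hi <- pmin(idx + 1L, length(mt))
      d_lo <- abs(t - mt[lo])
      d_hi <- abs(t - mt[hi])
      nearest <- ifelse(d_lo <= d_hi, lo, hi)
      near_ok <- pmin(d_lo, d_hi) <= tolerance_s
      drop <- !is_met & near_ok & met$value[nearest] < met_gate
      df[!drop, , drop = FALSE]
    }) %>%
    dplyr::ungroup() %>%
    dplyr::select(dplyr::all_of(names(samples))) %>%
    dplyr::arrange(.data$participant_id, .data$timestamp_local)
}

#' Annotate samples as awake or asleep
#'
#' Flags a sample asleep iff its timestamp falls in `[sleep_start,
#' sleep_end)` of one of that participant's selected sleep records; samples
#' on nights with no record are awake.
#'
#' @param samples Sample tibble.
#' @param sleep Output of [select_longest_sleep()].
#' @return `samples` with a logical `asleep` column.
#' @export
annotate_sleep <- function(samples, sleep) {
  samples %>%
    dplyr::group_by(.data$participant_id) %>%
    dplyr::group_modify(function(df, key) {
      iv <- sleep %>%
        dplyr::filter(.data$participant_id == key$participant_id) %>%
        dplyr::arrange(.data$sleep_start)
      if (nrow(iv) == 0) {
        df$asleep <- FALSE
        return(df)
      }
      i <- findInterval(as.numeric(df$timestamp_local),
                        as.numeric(iv$sleep_start))
      df$asleep <- i >= 1 &
        as.numeric(df$timestamp_local) <
          as.numeric(iv$sleep_end)[pmax(i, 1L)]
      df
    }) %>%
    dplyr::ungroup() %>%
    dplyr::select(dplyr::all_of(c(names(samples), "asleep")))
}

#' Daily aggregate statistics per modality and window
#'
#' For each (participant, pregnancy, date, modality) computes mean, median,
#' peak (mean of the sample values in the 90-95\% midpoint-rank band) and
#' trough (5-10\% band) over either the full civil day (`window = "h24"`) or
#' the nightly clock window `[20:00 of date, 08:00 of date+1)`
#' (`window = "nightly"`).  Empty groups emit no row.
#'
#' @param samples Cleaned sample tibble.
#' @param window `"h24"` or `"nightly"`.
#' @param config A [preprocess_config()].
#' @return Tibble with columns participant_id, pregnancy_id, date, window,
#'   modality, mean, median, peak, trough, n_samples.
#' @export
daily_aggregate <- function(samples, window = c("h24", "nightly"),
                            config = preprocess_config()) {
  window <- match.arg(window)
  hours <- as.integer(format(samples$timestamp_local, "%H"))
  dates <- as.Date(samples$timestamp_local)
  if (window == "nightly") {
    keep <- hours >= config$nightly_start | hours < config$nightly_end
    samples <- samples[keep, , drop = FALSE]
    dates <- dates[keep]
    hours <- hours[keep]
    dates[hours < config$nightly_end] <-
      dates[hours < config$nightly_end] - 1L
  }
  samples$date <- dates
  pk <- config$peak_band
  tr <- config$trough_band
  def <- config$peak_definition
  samples %>%
    dplyr::group_by(.data$participant_id, .data$pregnancy_id, .data$date,
                    .data$modality) %>%
    dplyr::summarise(
      mean = mean(.data$value),
      median = stats::median(.data$value),
      peak = gw_band_mean(.data$value, pk, def),
      trough = gw_band_mean(.data$value, tr, def),
      n_samples = dplyr::n(),
      .groups = "drop"
    ) %>%
    dplyr::mutate(window = window, .after = "date")
}

#' Run the full sample-cleaning pipeline
#'
#' Pipeline order: load/normalise, first-pass quantile filter (5-95\% per
#' participant), activity non-wear gate, sleep annotation, second-pass
#' quantile filter (2-98\% per participant and modality), then daily
#' aggregation at both 24-h and nightly resolutions.
#'
#' @param samples Raw sample tibble (or paths accepted by
#'   [load_and_normalize()]).
#' @param sleep Raw sleep-summary tibble.
#' @param config A [preprocess_config()].
#' @return Daily-aggregate tibble (both windows stacked).
#' @export
preprocess_samples <- function(samples, sleep,
                               config = preprocess_config()) {
  cleaned <- load_and_normalize(samples) %>%
    quantile_filter(config$first_pass_quantiles[1],
                    config$first_pass_quantiles[2],
                    scope = "per_participant") %>%
    met_gate_filter(config$met_gate, config$met_pair_tolerance_s) %>%
    annotate_sleep(select_longest_sleep(sleep)) %>%
    quantile_filter(config$second_pass_quantiles[1],
                    config$second_pass_quantiles[2],
                    scope = "per_participant_modality")
  dplyr::bind_rows(daily_aggregate(cleaned, "h24", config),
                   daily_aggregate(cleaned, "nightly", config))
}

#' Pivot wide daily aggregates to the canonical long format
#'
#' @param daily Output of [daily_aggregate()] / [preprocess_samples()].
#' @return Long tibble with a `statistic` column (mean/median/peak/trough)
#'   and a `value` column, matching the format emitted by
#'   [simulate_cohort()].
#' @export
daily_long <- function(daily) {
  daily %>%
    tidyr::pivot_longer(dplyr::all_of(c("mean", "median", "peak", "trough")),
                        names_to = "statistic", values_to = "value") %>%
    dplyr::select("participant_id", "pregnancy_id", "date", "window",
                  "modality", "statistic", "value")
}
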