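t0 <- as.POSIXct("2021-03-01 00:00:00", tz = "UTC")

test_that("loading collapses duplicates and sorts by participant and time", {
  s <- make_samples(t0 + c(120, 0, 60, 120, 0), c(5, 1, 3, 5, 1))
  out <- load_and_normalize(s)
  expect_equal(nrow(out), 3)
  expect_equal(out$value, c(1, 3, 5))
  expect_true(!is.unsorted(out$timestamp_local))
})

test_that("unparseable timestamps are rejected row-wise, en masse fatally", {
  s <- make_samples(t0 + 0:9 * 60, 1:10)
  s$timestamp_local <- as.character(s$timestamp_local)
  s$timestamp_local[1] <- "not-a-time"
  expect_message(out <- load_and_normalize(s), "dropped 1")
  expect_equal(nrow(out), 9)
  s$timestamp_local[1:3] <- "not-a-time"
  expect_error(load_and_normalize(s), "rejected")
})

test_that("longest sleep row wins, ties broken by earliest start", {
  sl <- tibble::tibble(
    participant_id = "p1", date = as.Date("2021-03-01"),
    sleep_start = t0 + c(22, 23, 21) * 3600,
    sleep_end = t0 + c(28, 31, 29) * 3600,
    duration_s = c(21600, 28800, 28800))
  out <- select_longest_sleep(sl)
  expect_equal(nrow(out), 1)
  expect_equal(out$duration_s, 28800)
  expect_equal(out$sleep_start, t0 + 21 * 3600)
  one <- sl[1, ]
  expect_identical(select_longest_sleep(one)[, names(one)], one)
})

test_that("quantile filter keeps exactly the interpolated in-band values", {
  s <- make_samples(t0 + (1:100) * 60, 1:100)
  out <- quantile_filter(s, 0.05, 0.95)
  expect_equal(sort(out$value), 6:95)  # Q(0.05)=5.95, Q(0.95)=95.05
  const <- make_samples(t0 + (1:20) * 60, rep(7, 20))
  expect_equal(nrow(quantile_filter(const, 0.05, 0.95)), 20)
  expect_equal(nrow(quantile_filter(s, 0, 1)), 100)
  expect_error(quantile_filter(s, 0.9, 0.1), "low < high")
})

test_that("quantile filter never removes more than (low + 1 - high) n + 2 per group", {
  withr::with_seed(8, {
    for (i in 1:25) {
      n <- sample(5:400, 1)
      s <- make_samples(t0 + (1:n) * 60, rnorm(n))
      out <- quantile_filter(s, 0.05, 0.95)
      expect_lte(n - nrow(out), 0.10 * n + 2)
    }
  })
})

test_that("the activity gate drops samples paired with sub-gate MET", {
  tt <- as.POSIXct("2021-03-01 02:00:00", tz = "UTC")
  s <- dplyr::bind_rows(
    make_samples(tt, 36.5, "temperature"),
    make_samples(tt, 0.4, "met"),
    make_samples(tt + 3600, 36.6, "temperature"),
    make_samples(tt + 3600, 0.5, "met"),       # exactly at gate: retained
    make_samples(tt + 7200, 36.7, "temperature"))  # no MET within 60 s
  out <- met_gate_filter(s)
  expect_false(36.5 %in% out$value)
  expect_true(36.6 %in% out$value)
  expect_true(36.7 %in% out$value)
  expect_true(all(c(0.4, 0.5) %in% out$value[out$modality == "met"]))
  no_met <- make_samples(tt + 0:5 * 60, rep(36.5, 6))
  expect_warning(out2 <- met_gate_filter(no_met), "no MET")
  expect_equal(nrow(out2), 6)
})

test_that("sleep annotation uses half-open intervals and defaults to awake", {
  sl <- select_longest_sleep(tibble::tibble(
    participant_id = "p1", date = as.Date("2021-03-01"),
    sleep_start = t0 + 23 * 3600, sleep_end = t0 + 31 * 3600,
    duration_s = 28800))
  s <- make_samples(t0 + c(22, 23, 30, 31, 50) * 3600, 1:5)
  out <- annotate_sleep(s, sl)
  expect_equal(out$asleep, c(FALSE, TRUE, TRUE, FALSE, FALSE))
})

test_that("daily peak and trough equal the rank-band means", {
  tt <- as.POSIXct("2021-03-01 20:00:00", tz = "UTC")
  s <- make_samples(tt + seq_len(200) * 3, sample(1:200))
  agg <- daily_aggregate(s, "nightly")
  expect_equal(agg$peak, mean(181:190))    # ranks with mid in [0.90, 0.95]
  expect_equal(agg$trough, mean(11:20))
  expect_equal(agg$n_samples, 200)
  const <- make_samples(tt + 1:50 * 60, rep(3.3, 50))
  cagg <- daily_aggregate(const, "nightly")
  expect_equal(c(cagg$mean, cagg$median, cagg$peak, cagg$trough),
               rep(3.3, 4))
})

test_that("nightly window is [20:00, 08:00) attributed to the evening date", {
  s <- make_samples(t0 + c(20 * 3600,             # 20:00 day 1 -> in
                           31 * 3600 + 3540,      # 07:59 day 2 -> in, day 1
                           32 * 3600,             # 08:00 day 2 -> out
                           12 * 3600), 1:4)       # noon -> out
  agg <- daily_aggregate(s, "nightly")
  expect_equal(nrow(agg), 1)
  expect_equal(agg$date, as.Date("2021-03-01"))
  expect_equal(agg$n_samples, 2)
  h24 <- daily_aggregate(s, "h24")
  expect_equal(sum(h24$n_samples), 4)
})

test_that("daily aggregates match the brute-force band oracle and ordering", {
  cfg <- preprocess_config()
  withr::with_seed(21, {
    for (i in 1:60) {
      n <- sample(1:500, 1)
      x <- rnorm(n)
      tt <- as.POSIXct("2021-03-01 21:00:00", tz = "UTC") + seq_len(n)
      agg <- daily_aggregate(make_samples(tt, x), "nightly", cfg)
      expect_equal(agg$peak, band_mean_oracle(x, cfg$peak_band))
      expect_equal(agg$trough, band_mean_oracle(x, cfg$trough_band))
      expect_true(agg$trough <= agg$median && agg$median <= agg$peak)
    }
  })
})

test_that("the endpoint-mean peak definition is available as a switch", {
  cfg <- preprocess_config(peak_definition = "endpoint_mean")
  tt <- as.POSIXct("2021-03-01 21:00:00", tz = "UTC")
  x <- 1:100
  agg <- daily_aggregate(make_samples(tt + seq_along(x), x), "nightly", cfg)
  expect_equal(agg$peak, mean(stats::quantile(x, c(0.90, 0.95), type = 7)))
})

test_that("the full cleaning pipeline composes the stages in order", {
  cfg <- sim_config(nonwear_rate = 0.1, missing_day_rate = 0)
  daily <- simulate_pregnancy_series(full_term_spec(), cfg, seed = 6)
  daily <- daily[daily$day %in% 0:2, ]
  st <- simulate_minute_stream(daily, cfg, seed = 12)
  pcfg <- preprocess_config()
  got <- suppressMessages(suppressWarnings(
    preprocess_samples(st$samples, st$sleep, pcfg)))
  manual <- suppressMessages(suppressWarnings({
    cleaned <- load_and_normalize(st$samples)
    cleaned <- quantile_filter(cleaned, 0.05, 0.95, "per_participant")
    cleaned <- met_gate_filter(cleaned, 0.5, 60)
    cleaned <- annotate_sleep(cleaned, select_longest_sleep(st$sleep))
    cleaned <- quantile_filter(cleaned, 0.02, 0.98,
                               "per_participant_modality")
    dplyr::bind_rows(daily_aggregate(cleaned, "h24", pcfg),
                     daily_aggregate(cleaned, "nightly", pcfg))
  }))
  expect_equal(got, manual)
  expect_true(all(got$trough <= got$median + 1e-12 &
                    got$median <= got$peak + 1e-12))
})

test_that("the activity gate removes nearly all samples in non-wear blocks", {
  cfg <- sim_config(nonwear_rate = 0.15, missing_day_rate = 0)
  daily <- simulate_pregnancy_series(full_term_spec(), cfg, seed = 7)
  daily <- daily[daily$day %in% 0:3, ]
  st <- simulate_minute_stream(daily, cfg, seed = 13)
  met <- st$samples[st$samples$modality == "met", ]
  block_minutes <- met$timestamp_local[met$value < 0.5]
  in_block <- st$samples$modality != "met" &
    st$samples$timestamp_local %in% block_minutes
  expect_gt(sum(in_block), 100)
  out <- met_gate_filter(st$samples)
  still <- out$modality != "met" & out$timestamp_local %in% block_minutes
  expect_lte(sum(still) / sum(in_block), 0.05)
})
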