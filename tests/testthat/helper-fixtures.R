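# Shared fixtures and independent oracles.  The fixture cohort is expensive
# (~700 survey rows, ~250 simulated pregnancies) so it is built once per
# session and cached.

gw_test_cache <- new.env(parent = emptyenv())

fixture_sim <- function(seed = 1) {
  key <- paste0("sim", seed)
  if (is.null(gw_test_cache[[key]])) {
    gw_test_cache[[key]] <-
      simulate_cohort(sim_config(), seed = seed, fixture = TRUE)
  }
  gw_test_cache[[key]]
}

fixture_cohort <- function(seed = 1) {
  key <- paste0("cohort", seed)
  if (is.null(gw_test_cache[[key]])) {
    sim <- fixture_sim(seed)
    gw_test_cache[[key]] <- suppressWarnings(
      build_cohort(sim$survey, sim$daily))
  }
  gw_test_cache[[key]]
}

noiseless_config <- function(...) {
  sim_config(noise_sd = c(temp_peak = 0, temp_trough = 0, hr = 0, hrv = 0,
                          rr = 0, met = 0),
             between_subject_sd = c(temp_peak = 0, temp_trough = 0, hr = 0,
                                    hrv = 0, rr = 0, met = 0),
             missing_day_rate = 0, nonwear_rate = 0, ...)
}

full_term_spec <- function(gestation_from_dkp = 245) {
  list(pregnancy_id = "g1", participant_id = "p1",
       dkp = as.Date("2021-01-01"),
       dps = as.Date("2021-01-01") + gestation_from_dkp,
       outcome = "delivered")
}

make_samples <- function(times, values, modality = "temperature",
                         participant_id = "p1", pregnancy_id = "g1") {
  tibble::tibble(participant_id = participant_id,
                 pregnancy_id = pregnancy_id,
                 timestamp_local = times, modality = modality,
                 value = values)
}

# Aligned long tibble for a single nightly peak-temperature series.
make_aligned <- function(day, value, pregnancy_id = "g1",
                         modality = "temperature", statistic = "peak",
                         window = "nightly") {
  tibble::tibble(pregnancy_id = pregnancy_id, day = day, window = window,
                 modality = modality, statistic = statistic, value = value)
}

# --- independent oracles -------------------------------------------------

# Exact two-sided Mann-Whitney p by full enumeration of all assignments of
# the pooled observations to the two samples.
mw_enum_p <- function(x, y) {
  n1 <- length(x)
  n <- n1 + length(y)
  r <- rank(c(x, y))
  obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(n, n1)
  us <- apply(combs, 2, function(ix) sum(r[ix])) - n1 * (n1 + 1) / 2
  min(1, 2 * min(mean(us <= obs), mean(us >= obs)))
}

# Monte-Carlo permutation p for the Kruskal-Wallis statistic (tie-free
# inputs assumed).
kw_perm_p <- function(values, groups, B = 40000, seed = 42) {
  r <- rank(values)
  n <- length(r)
  h_of <- function(g) {
    sums <- tapply(r, g, sum)
    sizes <- tapply(r, g, length)
    12 / (n * (n + 1)) * sum(sums^2 / sizes) - 3 * (n + 1)
  }
  obs <- h_of(groups)
  withr::with_seed(seed, {
    perm <- replicate(B, h_of(sample(groups)))
  })
  mean(perm >= obs - 1e-12)
}

# Brute-force daily peak/trough: sort, select the midpoint-rank band,
# average (interpolated band-midpoint quantile when the band is empty).
band_mean_oracle <- function(x, band) {
  s <- sort(x)
  n <- length(s)
  keep <- vapply(seq_len(n),
                 function(i) (i - 0.5) / n >= band[1] &&
                   (i - 0.5) / n <= band[2], logical(1))
  if (any(keep)) {
    mean(s[keep])
  } else {
    unname(stats::quantile(x, mean(band), type = 7))
  }
}
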