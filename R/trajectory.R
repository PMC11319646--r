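#' Pre-pregnancy baseline statistics for z-scoring
#'
#' Mean and sample SD of each pregnancy's daily values inside the baseline
#' window (days `[-60, -30)` relative to the day the pregnancy became
#' known).  A pregnancy-series is usable for z-scored analyses only with at
#' least `min_days` baseline days and a strictly positive SD.
#'
#' @param aligned DKP-aligned long tibble.
#' @param scheme An [alignment_scheme()].
#' @param min_days Minimum baseline days (default 5).
#' @return Tibble keyed by (pregnancy_id, window, modality, statistic) with
#'   `mu`, `sigma`, `n_days`, `usable`.
#' @export
baseline_stats <- function(aligned, scheme = alignment_scheme(),
                           min_days = 5) {
  bw <- scheme$baseline_window
  aligned %>%
    dplyr::filter(.data$day >= bw[1], .data$day < bw[2]) %>%
    dplyr::group_by(.data$pregnancy_id, .data$window, .data$modality,
                    .data$statistic) %>%
    dplyr::summarise(mu = mean(.data$value), sigma = stats::sd(.data$value),
                     n_days = dplyr::n(), .groups = "drop") %>%
    dplyr::mutate(usable = .data$n_days >= min_days &
                    !is.na(.data$sigma) & .data$sigma > 0)
}

#' Z-score aligned series against pre-pregnancy baselines
#'
#' Transforms every value as `z = (x - mu) / sigma` using that
#' pregnancy-series' baseline statistics.  Series whose baseline is unusable
#' (too few days or zero variance) are dropped with a message, mirroring the
#' exclusion of pregnancies lacking pre-onset data from normalised analyses.
#'
#' @param aligned DKP- or DPS-aligned long tibble.
#' @param stats Output of [baseline_stats()] (always computed on DKP-aligned
#'   data).
#' @return The aligned tibble with `value` replaced by its z-score.
#' @export
zscore_series <- function(aligned, stats) {
  usable <- stats %>% dplyr::filter(.data$usable)
  dropped <- aligned %>%
    dplyr::distinct(.data$pregnancy_id, .data$window, .data$modality,
                    .data$statistic) %>%
    dplyr::anti_join(usable, by = c("pregnancy_id", "window", "modality",
                                    "statistic"))
  if (nrow(dropped) > 0) {
    rlang::inform(sprintf(
      "zscore_series: dropped %d pregnancy-series without a usable baseline",
      nrow(dropped)))
  }
  aligned %>%
    dplyr::inner_join(usable %>% dplyr::select("pregnancy_id", "window",
                                               "modality", "statistic",
                                               "mu", "sigma"),
                      by = c("pregnancy_id", "window", "modality",
                             "statistic")) %>%
    dplyr::mutate(value = (.data$value - .data$mu) / .data$sigma) %>%
    dplyr::select(-"mu", -"sigma")
}

#' Trailing rolling mean over calendar days
#'
#' Smooths each pregnancy-series with a trailing mean over the last
#' `window_days` *calendar* days (not row positions), requiring at least one
#' observation in the window; the output day set equals the input day set,
#' so gappy wearable series keep their length.
#'
#' @param aligned Long aligned tibble.
#' @param window_days Window length in days (>= 1).
#' @return The smoothed tibble.
#' @export
rolling_mean <- function(aligned, window_days) {
  gw_assert(window_days >= 1, "`window_days` must be >= 1")
  if (window_days == 1) return(aligned)
  aligned %>%
    dplyr::group_by(dplyr::across(dplyr::any_of(
      c("pregnancy_id", "window", "modality", "statistic")))) %>%
    dplyr::arrange(.data$day, .by_group = TRUE) %>%
    dplyr::mutate(value = gw_roll_days(.data$day, .data$value,
                                       window_days)) %>%
    dplyr::ungroup()
}

#' Population trajectory profile
#'
#' Per aligned day and series: the cross-pregnancy median, interpolated
#' lower/upper quantiles (default 10/90\%), and a 95\% confidence interval
#' of the median from a seeded percentile bootstrap.  Days observed in fewer
#' than three pregnancies emit the median only.
#'
#' @param aligned Long aligned tibble (one value per pregnancy-series-day).
#' @param quantiles Length-2 vector of shading quantiles.
#' @param B Bootstrap resamples (default 1000).
#' @param seed Seed for the bootstrap.
#' @param conf Confidence level (default 0.95).
#' @return A tibble of class `gw_profile` (`window`, `modality`,
#'   `statistic`, `day`, `n`, `median`, `q_lo`, `q_hi`, `ci_lo`, `ci_hi`).
#' @export
population_profile <- function(aligned, quantiles = c(0.1, 0.9), B = 1000,
                               seed = 1, conf = 0.95) {
  gw_assert(nrow(aligned) > 0, "population_profile: empty input")
  a <- (1 - conf) / 2
  res <- withr::with_seed(seed, {
    aligned %>%
      dplyr::group_by(.data$window, .data$modality, .data$statistic,
                      .data$day) %>%
      dplyr::summarise(
        n = dplyr::n(),
        median = stats::median(.data$value),
        q_lo = if (dplyr::n() >= 3) gw_quantile(.data$value, quantiles[1])
               else NA_real_,
        q_hi = if (dplyr::n() >= 3) gw_quantile(.data$value, quantiles[2])
               else NA_real_,
        boot = if (dplyr::n() >= 3) {
          x <- .data$value
          bm <- apply(matrix(sample(x, length(x) * B, replace = TRUE),
                             ncol = B), 2, stats::median)
          list(gw_quantile(bm, c(a, 1 - a)))
        } else list(c(NA_real_, NA_real_)),
        .groups = "drop"
      )
  })
  res %>%
    dplyr::mutate(ci_lo = purrr::map_dbl(.data$boot, 1),
                  ci_hi = purrr::map_dbl(.data$boot, 2)) %>%
    dplyr::select(-"boot") %>%
    structure(class = c("gw_profile", class(tibble::tibble())))
}

#' Per-pregnancy trimester means
#'
#' Mean of the available daily values inside each trimester window
#' (including the pre-pregnancy trimester "t-1" and postpartum "t4");
#' trimesters with no observed days are omitted.
#'
#' @param aligned DKP-aligned long tibble.
#' @param scheme An [alignment_scheme()].
#' @return Tibble (`pregnancy_id`, series keys, `trimester`, `mean`,
#'   `n_days`).
#' @export
trimester_means <- function(aligned, scheme = alignment_scheme()) {
  win <- scheme$trimester_windows
  aligned %>%
    dplyr::inner_join(win, by = dplyr::join_by(day >= start, day < end)) %>%
    dplyr::group_by(.data$pregnancy_id, .data$window, .data$modality,
                    .data$statistic, .data$trimester) %>%
    dplyr::summarise(mean = mean(.data$value), n_days = dplyr::n(),
                     .groups = "drop")
}

#' Mann-Whitney-Wilcoxon rank test with significance annotation
#'
#' Two-sided Mann-Whitney U via [stats::wilcox.test()]: the exact
#' distribution when both samples are small and tie-free, otherwise the
#' tie-corrected normal approximation with continuity correction.  The
#' annotation uses the conventional star ladder Bonferroni-corrected for
#' `m_comparisons` tests (`*` at `p <= 0.05/m`).
#'
#' @param x,y Numeric samples.
#' @param m_comparisons Number of comparisons for the Bonferroni annotation
#'   (default 4, the number of adjacent-trimester contrasts).
#' @return One-row tibble: `U`, `p`, `n1`, `n2`, `annotation`.
#' @export
mann_whitney_u <- function(x, y, m_comparisons = 4) {
  gw_assert(length(x) >= 1 && length(y) >= 1,
            "both samples must be non-empty")
  ht <- suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided",
                                            correct = TRUE))
  tibble::tibble(U = unname(ht$statistic), p = ht$p.value,
                 n1 = length(x), n2 = length(y),
                 annotation = gw_annotate_p(ht$p.value, m_comparisons))
}

#' Adjacent-trimester rank tests
#'
#' One Mann-Whitney test per adjacent trimester pair -- (t-1 vs t1),
#' (t1 vs t2), (t2 vs t3), (t3 vs t4) -- on the per-pregnancy trimester
#' means, annotated with the Bonferroni-corrected ladder for the four
#' comparisons.  A comparison is omitted (with a warning) when either
#' trimester has fewer than two pregnancies.
#'
#' @param tmeans Output of [trimester_means()].
#' @return Tibble with series keys, `comparison`, `U`, `p`, `n1`, `n2`,
#'   `annotation`.
#' @export
pairwise_trimester_tests <- function(tmeans) {
  pairs <- list(c("t-1", "t1"), c("t1", "t2"), c("t2", "t3"), c("t3", "t4"))
  tmeans %>%
    dplyr::group_by(.data$window, .data$modality, .data$statistic) %>%
    dplyr::group_modify(function(df, key) {
      purrr::map(pairs, function(pr) {
        x <- df$mean[df$trimester == pr[1]]
        y <- df$mean[df$trimester == pr[2]]
        if (length(x) < 2 || length(y) < 2) {
          rlang::warn(sprintf("comparison %s vs %s omitted (< 2 pregnancies)",
                              pr[1], pr[2]))
          return(NULL)
        }
        mann_whitney_u(x, y) %>%
          dplyr::mutate(comparison = paste(pr[1], "vs", pr[2]), .before = 1)
      }) %>% dplyr::bind_rows()
    }) %>%
    dplyr::ungroup()
}

#' Map survey age bins to the advanced-maternal-age dichotomy
#'
#' Bins "20-24", "25-29", "30-34" map to `"<35"`; "35-39", "40-44", "45-49"
#' to `">=35"` (the conventional advanced-maternal-age threshold).
#'
#' @param age_bin Character vector of survey age-bin labels.
#' @return Character vector `"<35"` / `">=35"`.
#' @export
age_group <- function(age_bin) {
  lower <- suppressWarnings(as.integer(sub("-.*", "", age_bin)))
  dplyr::if_else(lower < 35, "<35", ">=35")
}

#' Age-threshold trajectory comparisons
#'
#' Splits pregnancies at the advanced-maternal-age threshold (35 years) and
#' tests, per time bin and series, the per-pregnancy bin means between the
#' groups with a two-sided Mann-Whitney test, Bonferroni-corrected across
#' the bins within each series.  Bins where either group is empty are
#' skipped.
#'
#' @param aligned DKP-aligned long tibble (typically z-scored).
#' @param records Data frame with `pregnancy_id` and `age_bin`.
#' @param bin_weeks Bin width in weeks (1 or 4).
#' @param day_range Aligned-day range analysed (default `c(-28, 252)`,
#'   conception through 40 weeks).
#' @return Tibble with series keys, `bin_start_day`, group sizes, `U`, `p`,
#'   `p_adj`, `significant`.
#' @export
age_threshold_comparison <- function(aligned, records, bin_weeks = 1,
                                     day_range = c(-28, 252)) {
  gw_assert(bin_weeks %in% c(1, 4), "`bin_weeks` must be 1 or 4")
  width <- 7L * bin_weeks
  groups <- records %>%
    dplyr::mutate(age_group = age_group(.data$age_bin)) %>%
    dplyr::select("pregnancy_id", "age_group")
  binned <- aligned %>%
    dplyr::filter(.data$day >= day_range[1], .data$day <= day_range[2]) %>%
    dplyr::inner_join(groups, by = "pregnancy_id") %>%
    dplyr::mutate(bin_start_day =
                    (floor((.data$day - day_range[1]) / width)) * width +
                    day_range[1]) %>%
    dplyr::group_by(.data$window, .data$modality, .data$statistic,
                    .data$bin_start_day, .data$age_group,
                    .data$pregnancy_id) %>%
    dplyr::summarise(mean = mean(.data$value), .groups = "drop")
  res <- binned %>%
    dplyr::group_by(.data$window, .data$modality, .data$statistic,
                    .data$bin_start_day) %>%
    dplyr::group_modify(function(df, key) {
      x <- df$mean[df$age_group == "<35"]
      y <- df$mean[df$age_group == ">=35"]
      if (length(x) == 0 || length(y) == 0) return(tibble::tibble())
      mann_whitney_u(x, y) %>% dplyr::select(-"annotation")
    }) %>%
    dplyr::ungroup()
  if (!"p" %in% names(res)) {
    return(tibble::tibble(window = character(), modality = character(),
                          statistic = character(), bin_start_day = double(),
                          U = double(), p = double(), n1 = integer(),
                          n2 = integer(), p_adj = double(),
                          significant = logical()))
  }
  res %>%
    dplyr::group_by(.data$window, .data$modality, .data$statistic) %>%
    dplyr::mutate(p_adj = pmin(1, .data$p * dplyr::n()),
                  significant = .data$p_adj <= 0.05) %>%
    dplyr::ungroup()
}
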