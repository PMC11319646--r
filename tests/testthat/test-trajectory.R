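test_that("baseline statistics use the [-60, -30) window with sample SD", {
  aligned <- make_aligned(c(-60, -45, -31, -29, 10),
                          c(36.0, 36.2, 36.4, 99, 99))
  bs <- baseline_stats(aligned, min_days = 3)
  expect_equal(bs$mu, 36.2)
  expect_equal(bs$sigma, 0.2, tolerance = 1e-12)
  expect_equal(bs$n_days, 3)
  expect_true(bs$usable)
})

test_that("constant or short baselines are flagged unusable", {
  const <- make_aligned(-60:-41, rep(36.2, 20))
  expect_false(baseline_stats(const)$usable)
  short <- make_aligned(c(-60, -55, -50, -45), c(36, 36.1, 36.2, 36.3))
  expect_false(baseline_stats(short)$usable)   # 4 days < 5
})

test_that("z-scoring is the exact affine transform and self-normalising", {
  aligned <- make_aligned(c(-60:-31, 0:9),
                          c(rnorm(30, 36.2, 0.2), rnorm(10, 36.6, 0.2)))
  bs <- baseline_stats(aligned)
  z <- zscore_series(aligned, bs)
  x <- aligned$value[aligned$day == 0]
  expect_equal(z$value[z$day == 0], (x - bs$mu) / bs$sigma)
  zb <- z$value[z$day >= -60 & z$day < -30]
  expect_lt(abs(mean(zb)), 1e-9)
  expect_equal(sd(zb), 1, tolerance = 1e-9)
  # z-scoring the z-scores against their own baseline is the identity
  z2 <- zscore_series(z, baseline_stats(z))
  expect_equal(z2$value, z$value, tolerance = 1e-9)
})

test_that("hand-checked z-score example", {
  aligned <- make_aligned(c(-60, -50, -40, -35, -31, 5),
                          c(36.0, 36.2, 36.4, 36.2, 36.2, 36.4))
  bs <- baseline_stats(aligned)
  z <- zscore_series(aligned, bs)
  expect_equal(z$value[z$day == 5], (36.4 - bs$mu) / bs$sigma)
  # unusable baseline drops the series with a message
  const <- make_aligned(-60:-31, rep(1, 30), pregnancy_id = "g9")
  expect_message(out <- zscore_series(const, baseline_stats(const)),
                 "without a usable baseline")
  expect_equal(nrow(out), 0)
})

test_that("rolling means trail over calendar days, not rows", {
  aligned <- make_aligned(1:3, c(1, 2, 3))
  expect_equal(rolling_mean(aligned, 1), aligned)
  sm <- rolling_mean(aligned, 3)
  expect_equal(sm$value[sm$day == 3], 2)
  expect_equal(sm$value[sm$day == 1], 1)      # partial window
  # a gap: day 10 sees only itself within the trailing 3 days
  gappy <- make_aligned(c(1, 2, 10, 11), c(1, 3, 10, 20))
  sm2 <- rolling_mean(gappy, 3)
  expect_equal(sm2$value[sm2$day == 10], 10)
  expect_equal(sm2$value[sm2$day == 11], 15)
  expect_equal(sm2$day, gappy$day)            # day set preserved
})

test_that("population profile matches interpolated quantiles and brute force", {
  three <- dplyr::bind_rows(
    make_aligned(0, 1, "a"), make_aligned(0, 2, "b"),
    make_aligned(0, 3, "c"))
  pr <- population_profile(three, B = 200, seed = 1)
  expect_equal(pr$median, 2)
  expect_equal(pr$q_lo, 1.2)   # type-7 Q(0.1) of {1,2,3}
  expect_equal(pr$q_hi, 2.8)
  expect_true(pr$ci_lo <= pr$median && pr$median <= pr$ci_hi)

  withr::with_seed(5, {
    many <- purrr::map(1:7, function(i) {
      make_aligned(1:20, rnorm(20), sprintf("g%d", i))
    }) %>% dplyr::bind_rows()
  })
  pr2 <- population_profile(many, B = 50, seed = 2)
  brute <- sapply(1:20, function(d) {
    sort(many$value[many$day == d])[4]  # middle of 7 sorted values
  })
  expect_equal(pr2$median[order(pr2$day)], brute)

  # seeded bootstrap is reproducible; n < 3 emits the median only
  pr3 <- population_profile(many, B = 50, seed = 2)
  expect_identical(pr2, pr3)
  single <- make_aligned(0:5, 1:6)
  pr4 <- population_profile(single, B = 20, seed = 1)
  expect_true(all(is.na(pr4$ci_lo)))
  expect_equal(pr4$median, as.numeric(1:6))
  expect_error(population_profile(single[0, ]), "empty")
})

test_that("trimester means average the available days per window", {
  aligned <- make_aligned(-28:62, 1:91)
  tm <- trimester_means(aligned)
  expect_equal(tm$trimester, "t1")
  expect_equal(tm$mean, 46)
  const <- make_aligned(c(70, 100, 150), rep(36.3, 3))
  tm2 <- trimester_means(const)
  expect_equal(tm2$trimester, "t2")
  expect_equal(tm2$mean, 36.3)        # t1/t3 omitted: no observed days
})

test_that("Mann-Whitney results match hand enumeration", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p, 0.1)              # 2/20 arrangements as extreme
  same <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p, 1)
  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
})

test_that("exact path agrees with the enumeration oracle for all small cases", {
  sizes <- list(c(3, 3), c(3, 4), c(3, 5), c(4, 4), c(4, 5), c(5, 5))
  for (sz in sizes) {
    n1 <- sz[1]; n2 <- sz[2]; n <- n1 + n2
    picks <- utils::combn(n, n1)
    for (j in seq_len(ncol(picks))) {
      x <- picks[, j]
      y <- setdiff(seq_len(n), x)
      got <- mann_whitney_u(x, y)
      expect_equal(got$p, mw_enum_p(x, y), tolerance = 1e-12)
      expect_true(got$U >= 0 && got$U <= n1 * n2)
    }
  }
})

test_that("normal approximation stays close to the exact path at n = 8", {
  withr::with_seed(33, {
    for (i in 1:10) {
      x <- rnorm(8); y <- rnorm(8, 0.5)
      exact <- mw_enum_p(x, y)
      approx_p <- suppressWarnings(
        stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value)
      expect_lt(abs(approx_p - exact), 0.01)
    }
  })
})

test_that("annotation ladder uses the Bonferroni-corrected boundaries", {
  ann <- gestwear:::gw_annotate_p
  expect_equal(ann(0.0125), "*")      # boundary = 0.05 / 4
  expect_equal(ann(0.01251), "ns")
  expect_equal(ann(2.5e-3), "**")
  expect_equal(ann(2.5e-4), "***")
  expect_equal(ann(2.5e-5), "****")
})

test_that("adjacent-trimester tests cover the four contrasts", {
  withr::with_seed(9, {
    tm <- tidyr::crossing(pregnancy_id = sprintf("g%02d", 1:12),
                          window = "nightly", modality = "temperature",
                          statistic = "peak",
                          trimester = c("t-1", "t1", "t2", "t3", "t4")) %>%
      dplyr::mutate(mean = rnorm(dplyr::n(),
                                 ifelse(trimester == "t1", 36.6, 36.3),
                                 0.05))
  })
  res <- pairwise_trimester_tests(tm)
  expect_equal(res$comparison,
               c("t-1 vs t1", "t1 vs t2", "t2 vs t3", "t3 vs t4"))
  expect_true(all(res$n1 == 12 & res$n2 == 12))
  expect_true(res$annotation[res$comparison == "t-1 vs t1"] != "ns")
  # a missing trimester drops its comparisons with a warning
  expect_warning(pairwise_trimester_tests(
    tm[tm$trimester != "t4", ]), "omitted")
})

test_that("age comparison flags an injected offset and skips empty groups", {
  withr::with_seed(13, {
    aligned <- purrr::map(1:12, function(i) {
      make_aligned(0:27, rnorm(28, ifelse(i <= 6, 0, 1), 0.3),
                   sprintf("g%02d", i))
    }) %>% dplyr::bind_rows()
  })
  rec <- tibble::tibble(pregnancy_id = sprintf("g%02d", 1:12),
                        age_bin = rep(c("30-34", "35-39"), each = 6))
  res <- age_threshold_comparison(aligned, rec, bin_weeks = 1,
                                  day_range = c(0, 27))
  expect_equal(nrow(res), 4)
  expect_true(mean(res$significant) >= 0.75)  # +1 z offset is detected
  one <- age_threshold_comparison(aligned[aligned$pregnancy_id == "g01", ],
                                  rec[1, ], bin_weeks = 1,
                                  day_range = c(0, 27))
  expect_equal(nrow(one), 0)
})
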