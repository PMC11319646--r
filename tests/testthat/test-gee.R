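# helper: build a prepared-series tibble directly
zrows <- function(id, day, z) tibble::tibble(pregnancy_id = id, day = day,
                                             z = z)

test_that("interior gaps are linearly interpolated, never extrapolated", {
  base_days <- -60:-31
  withr::with_seed(3, base_vals <- rnorm(30, 36.3, 0.1))
  aligned <- make_aligned(c(base_days, 0, 2), c(base_vals, 1, 3))
  out <- prepare_gee_series(aligned, smooth_days = 1)
  # midpoint of the {0: 1, 2: 3} gap is 2 before z-scoring
  mu <- mean(base_vals); sg <- sd(base_vals)
  expect_equal(out$z[out$day == 1], (2 - mu) / sg, tolerance = 1e-12)
  expect_equal(range(out$day), c(-60, 2))        # no extrapolation
  # gap-free series pass through the interpolation unchanged
  nogap <- make_aligned(c(base_days, 0:3), c(base_vals, 1:4))
  out2 <- prepare_gee_series(nogap, smooth_days = 1)
  expect_equal(out2$z[out2$day >= 0], (1:4 - mu) / sg, tolerance = 1e-12)
})

test_that("pregnancies without pre-onset data drop from the prepared set", {
  good <- make_aligned(c(-60:-31, 0:6), c(rnorm(30, 36.3, 0.1), rep(36.6, 7)),
                       pregnancy_id = "good")
  bare <- make_aligned(0:6, rep(36.6, 7), pregnancy_id = "bare")
  expect_message(out <- prepare_gee_series(dplyr::bind_rows(good, bare)),
                 "1 pregnancies dropped")
  expect_setequal(unique(out$pregnancy_id), "good")
})

test_that("length groups use the smallest strictly greater threshold", {
  expect_equal(assign_length_group(10), 14)
  expect_equal(assign_length_group(14), 28)   # strict boundary
  expect_equal(assign_length_group(55), 60)
  expect_equal(assign_length_group(c(13, 27, 39, 59)), c(14, 28, 40, 60))
  expect_error(assign_length_group(61), "exceeds")
  expect_equal(assign_length_group(60, thresholds = c(14, 28, 40, 63)), 63)
})

test_that("control sampling is deterministic with coverage screening", {
  zs <- dplyr::bind_rows(purrr::map(sprintf("c%d", 1:8), function(id) {
    zrows(id, 0:40, rnorm(41))
  }))
  efl <- tibble::tibble(pregnancy_id = "e1", dps_day = 10L)
  s1 <- sample_controls(efl, sprintf("c%d", 1:8), zs, k = 5, seed = 4)
  s2 <- sample_controls(efl, sprintf("c%d", 1:8), zs, k = 5, seed = 4)
  expect_identical(s1, s2)
  expect_equal(nrow(s1), 5)
  expect_equal(dplyr::n_distinct(s1$control_id), 5)
  # a pool of exactly k returns the pool regardless of seed
  s3 <- sample_controls(efl, sprintf("c%d", 1:5), zs, k = 5, seed = 99)
  expect_setequal(s3$control_id, sprintf("c%d", 1:5))
  # coverage shortfall is an explicit error
  short <- zs[zs$day <= 12 | zs$pregnancy_id %in% c("c1", "c2"), ]
  expect_error(sample_controls(efl, sprintf("c%d", 1:8), short, k = 5,
                               seed = 1),
               "coverage-eligible")
})

test_that("the dataset is balanced and calendar-aligned", {
  zs <- dplyr::bind_rows(
    purrr::map(sprintf("c%d", 1:10), function(id) zrows(id, 0:70,
                                                        rnorm(71))),
    zrows("e1", 0:20, rnorm(21)), zrows("e2", 0:60, rnorm(61)))
  efl <- tibble::tibble(pregnancy_id = c("e1", "e2"), dps_day = c(10L, 50L))
  ds <- build_gee_dataset(efl, sprintf("c%d", 1:10), zs, k = 5, seed = 2)
  expect_equal(nrow(ds), (2 + 10) * 7)          # 7 x series x (1 + k)
  expect_equal(attr(ds, "dropped_rows"), 0)
  expect_equal(sort(unique(ds$day)), 0:6)
  expect_setequal(unique(ds$length_threshold), c(14, 60))
  # row-wise: control offset j equals the anchor's DPS day + j in source
  ctl <- ds[ds$category == 1, ]
  anchor_day <- efl$dps_day[match(ctl$efl_anchor_id, efl$pregnancy_id)]
  src <- dplyr::left_join(
    ctl %>% dplyr::mutate(src_day = anchor_day + day),
    zs, by = c("pregnancy_id", "src_day" = "day"))
  expect_equal(src$z.x, src$z.y)
  # k = 0 keeps only the losses' own rows
  ds0 <- build_gee_dataset(efl, character(), zs, k = 0, seed = 2)
  expect_equal(nrow(ds0), 14)
  expect_true(all(ds0$category == 0))
})

test_that("an all-zero response yields all-zero coefficients", {
  zs <- dplyr::bind_rows(purrr::map(sprintf("c%d", 1:6),
                                    function(id) zrows(id, 0:30, 0)),
                         zrows("e1", 0:10, 0), zrows("e2", 0:30, 0))
  efl <- tibble::tibble(pregnancy_id = c("e1", "e2"), dps_day = c(4L, 20L))
  ds <- build_gee_dataset(efl, sprintf("c%d", 1:6), zs, k = 3, seed = 1)
  fit <- fit_gee(ds)
  expect_equal(tidy(fit)$estimate, rep(0, 8))
})

test_that("independence estimates equal OLS with cluster-robust errors", {
  skip_if_not_installed("sandwich")
  withr::with_seed(41, {
    zs <- dplyr::bind_rows(
      purrr::map(sprintf("c%d", 1:12), function(id) {
        zrows(id, 0:70, rnorm(71, 0, 1))
      }),
      zrows("e1", 0:15, rnorm(16, 2, 1)), zrows("e2", 0:35, rnorm(36, 2, 1)),
      zrows("e3", 0:55, rnorm(56, 2, 1)))
  })
  efl <- tibble::tibble(pregnancy_id = c("e1", "e2", "e3"),
                        dps_day = c(5L, 25L, 45L))
  ds <- build_gee_dataset(efl, sprintf("c%d", 1:12), zs, k = 4, seed = 3)
  fit <- fit_gee(ds, corstr = "independence")
  fm <- stats::lm(z ~ day * category * length_threshold, data = ds)
  expect_equal(tidy(fit)$estimate, unname(stats::coef(fm)),
               tolerance = 1e-10)
  vc <- sandwich::vcovCL(fm, cluster = ds$series_id, type = "HC0",
                         cadjust = FALSE)
  expect_equal(tidy(fit)$std.error, unname(sqrt(diag(vc))),
               tolerance = 1e-8)
})

test_that("fits are invariant to row order", {
  withr::with_seed(43, {
    zs <- dplyr::bind_rows(
      purrr::map(sprintf("c%d", 1:10), function(id) zrows(id, 0:70,
                                                          rnorm(71))),
      zrows("e1", 0:30, rnorm(31)), zrows("e2", 0:40, rnorm(41)),
      zrows("e3", 0:60, rnorm(61)))
  })
  efl <- tibble::tibble(pregnancy_id = c("e1", "e2", "e3"),
                        dps_day = c(20L, 35L, 50L))
  ds <- build_gee_dataset(efl, sprintf("c%d", 1:10), zs, k = 5, seed = 5)
  shuffled <- withr::with_seed(7, ds[sample.int(nrow(ds)), ])
  for (cs in c("independence", "exchangeable")) {
    f1 <- fit_gee(ds, corstr = cs)
    f2 <- fit_gee(shuffled, corstr = cs)
    expect_equal(tidy(f1)$estimate, tidy(f2)$estimate, tolerance = 1e-10)
    expect_equal(tidy(f1)$std.error, tidy(f2)$std.error, tolerance = 1e-10)
  }
})

test_that("balanced clusters make the exchangeable fit coincide with OLS", {
  # with equal cluster sizes and cluster-constant covariates in the design,
  # the exchangeable estimating equations are solved by the OLS coefficients
  withr::with_seed(47, {
    zs <- dplyr::bind_rows(
      purrr::map(sprintf("c%d", 1:8), function(id) zrows(id, 0:70,
                                                         rnorm(71))),
      zrows("e1", 0:30, rnorm(31)), zrows("e2", 0:60, rnorm(61)))
  })
  efl <- tibble::tibble(pregnancy_id = c("e1", "e2"), dps_day = c(20L, 50L))
  ds <- build_gee_dataset(efl, sprintf("c%d", 1:8), zs, k = 3, seed = 5)
  fi <- fit_gee(ds, corstr = "independence")
  fe <- fit_gee(ds, corstr = "exchangeable")
  expect_equal(tidy(fe)$estimate, tidy(fi)$estimate, tolerance = 1e-8)
  # on unbalanced clusters the two working structures genuinely differ
  ds_un <- ds[-c(1, 9, 17, 30), ]
  fu <- fit_gee(ds_un, corstr = "exchangeable")
  expect_s3_class(fu, "gw_gee")
  expect_true(abs(fu$alpha) <= 1)
})

test_that("one observation per cluster reduces to ordinary least squares", {
  withr::with_seed(53, {
    df <- tibble::tibble(series_id = sprintf("s%02d", 1:40),
                         day = sample(0:6, 40, TRUE),
                         category = rep(0:1, 20),
                         length_threshold = sample(c(14, 28, 40, 60), 40,
                                                   TRUE))
    df$z <- 1 + 0.3 * df$day - 0.2 * df$category + rnorm(40, 0, 0.5)
  })
  for (cs in c("independence", "exchangeable")) {
    fit <- fit_gee(df, corstr = cs)
    fm <- stats::lm(z ~ day * category * length_threshold, data = df)
    expect_equal(tidy(fit)$estimate, unname(stats::coef(fm)),
                 tolerance = 1e-8)
  }
})

test_that("a single length group is rejected as rank deficient", {
  zs <- dplyr::bind_rows(purrr::map(sprintf("c%d", 1:6),
                                    function(id) zrows(id, 0:20, rnorm(21))),
                         zrows("e1", 0:10, rnorm(11)),
                         zrows("e2", 0:10, rnorm(11)))
  efl <- tibble::tibble(pregnancy_id = c("e1", "e2"), dps_day = c(5L, 6L))
  ds <- build_gee_dataset(efl, sprintf("c%d", 1:6), zs, k = 3, seed = 1)
  expect_error(fit_gee(ds), "rank deficient")
})

test_that("tidy and glance expose the eight model terms and fit metadata", {
  withr::with_seed(59, {
    zs <- dplyr::bind_rows(
      purrr::map(sprintf("c%d", 1:10), function(id) zrows(id, 0:70,
                                                          rnorm(71))),
      zrows("e1", 0:30, rnorm(31)), zrows("e2", 0:40, rnorm(41)),
      zrows("e3", 0:60, rnorm(61)))
  })
  efl <- tibble::tibble(pregnancy_id = c("e1", "e2", "e3"),
                        dps_day = c(20L, 35L, 50L))
  ds <- build_gee_dataset(efl, sprintf("c%d", 1:10), zs, k = 5, seed = 5)
  fit <- fit_gee(ds)
  td <- tidy(fit)
  expect_equal(td$term,
               c("Intercept", "Day", "Category", "Length threshold",
                 "Day:Category", "Day:Length threshold",
                 "Category:Length threshold",
                 "Day:Category:Length threshold"))
  expect_true(all(td$conf.low <= td$estimate & td$estimate <= td$conf.high))
  gl <- glance(fit)
  expect_equal(gl$n_groups, 18)
  expect_equal(gl$n_obs, nrow(ds))
})
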