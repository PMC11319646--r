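#' Prepare nightly peak-temperature series for the loss analysis
#'
#' For each pregnancy: interior gaps of the DKP-aligned nightly
#' peak-temperature series are linearly interpolated (no extrapolation
#' beyond the observed ends), a trailing 3-day rolling mean is applied, and
#' the result is z-scored against the pre-pregnancy baseline window.
#' Pregnancies without a usable baseline (fewer than `min_days` baseline
#' days of the smoothed series, or zero variance) are excluded with a
#' message -- mirroring the exclusion of losses lacking pre-onset data.
#'
#' @param aligned DKP-aligned long tibble.
#' @param scheme An [alignment_scheme()].
#' @param smooth_days Trailing smoothing window (default 3).
#' @param min_days Minimum usable baseline days (default 5).
#' @return Tibble (`pregnancy_id`, `day`, `z`).
#' @export
prepare_gee_series <- function(aligned, scheme = alignment_scheme(),
                               smooth_days = 3, min_days = 5) {
  tp <- aligned %>%
    dplyr::filter(.data$modality == "temperature",
                  .data$statistic == "peak", .data$window == "nightly")
  filled <- tp %>%
    dplyr::group_by(.data$pregnancy_id) %>%
    dplyr::arrange(.data$day, .by_group = TRUE) %>%
    dplyr::group_modify(function(df, key) {
      grid <- seq(min(df$day), max(df$day))
      tibble::tibble(day = grid,
                     value = stats::approx(df$day, df$value, xout = grid,
                                           ties = "ordered")$y)
    }) %>%
    dplyr::mutate(value = gw_roll_days(.data$day, .data$value, smooth_days)) %>%
    dplyr::ungroup()
  bw <- scheme$baseline_window
  stats <- filled %>%
    dplyr::filter(.data$day >= bw[1], .data$day < bw[2]) %>%
    dplyr::group_by(.data$pregnancy_id) %>%
    dplyr::summarise(mu = mean(.data$value), sigma = stats::sd(.data$value),
                     n_days = dplyr::n(), .groups = "drop") %>%
    dplyr::filter(.data$n_days >= min_days, !is.na(.data$sigma),
                  .data$sigma > 0)
  dropped <- setdiff(unique(filled$pregnancy_id), stats$pregnancy_id)
  if (length(dropped) > 0) {
    rlang::inform(sprintf(
      "prepare_gee_series: %d pregnancies dropped (no usable baseline)",
      length(dropped)))
  }
  filled %>%
    dplyr::inner_join(stats, by = "pregnancy_id") %>%
    dplyr::mutate(z = (.data$value - .data$mu) / .data$sigma) %>%
    dplyr::select("pregnancy_id", "day", "z")
}

#' Assign a pregnancy-length threshold group
#'
#' Returns, per pregnancy, the smallest threshold strictly greater than the
#' pregnancy length in days from the day the pregnancy became known to the
#' day it stopped.  A length of exactly 14 therefore falls in the 28 group.
#'
#' @param length_days Integer vector of pregnancy lengths (DPS - DKP).
#' @param thresholds Ordered thresholds (default `c(14, 28, 40, 60)`; the
#'   variant `c(14, 28, 40, 63)` is one argument away).
#' @return Numeric vector of threshold values.
#' @export
assign_length_group <- function(length_days, thresholds = c(14, 28, 40, 60)) {
  thresholds <- sort(thresholds)
  idx <- findInterval(length_days, thresholds,
                      left.open = FALSE) + 1L
  # findInterval counts thresholds <= length; strict "greater than" means a
  # length equal to a threshold moves up to the next group.
  if (any(idx > length(thresholds))) {
    bad <- which(idx > length(thresholds))
    rlang::abort(sprintf(
      "pregnancy length %s exceeds the largest threshold %s",
      paste(length_days[bad], collapse = ", "), max(thresholds)))
  }
  thresholds[idx]
}

#' Sample time-matched full-term controls for each loss
#'
#' Draws `k` distinct full-term control pregnancies per loss, restricted to
#' controls whose prepared series covers the loss's matched 7-day window;
#' controls may be reused across different losses.  Deterministic under
#' `seed`.
#'
#' @param efl Tibble of included losses: `pregnancy_id`, `dps_day` (the
#'   loss's DPS as a DKP-aligned day index).
#' @param pool Character vector of full-term candidate ids.
#' @param zseries Prepared series ([prepare_gee_series()]) covering the
#'   candidates.
#' @param k Controls per loss (default 5).
#' @param seed Integer seed.
#' @return Tibble (`efl_id`, `dps_day`, `control_id`), `k` rows per loss.
#' @export
sample_controls <- function(efl, pool, zseries, k = 5, seed = 1) {
  cover <- zseries %>% dplyr::filter(.data$pregnancy_id %in% pool)
  withr::with_seed(seed, {
    purrr::map(seq_len(nrow(efl)), function(i) {
      L <- efl$dps_day[i]
      need <- seq(L, L + 6L)
      ok <- cover %>%
        dplyr::filter(.data$day %in% need) %>%
        dplyr::count(.data$pregnancy_id) %>%
        dplyr::filter(.data$n == 7L) %>%
        dplyr::pull("pregnancy_id")
      if (length(ok) < k) {
        rlang::abort(sprintf(
          "loss %s: only %d of %d required coverage-eligible controls",
          efl$pregnancy_id[i], length(ok), k))
      }
      tibble::tibble(efl_id = efl$pregnancy_id[i], dps_day = L,
                     control_id = sort(ok)[sample.int(length(ok), k)])
    }) %>% dplyr::bind_rows()
  })
}

#' Build the time-matched loss-vs-full-term dataset
#'
#' For each included loss: its own 7 days following the day the pregnancy
#' stopped (day offsets 0..6) plus the calendar-aligned 7-day windows of its
#' `k` sampled controls.  `category` is 0 for a loss and 1 for a full-term
#' control; `length_threshold` is the loss's pregnancy-length group, shared
#' by its controls.  Rows whose response is missing are dropped and counted
#' in the `dropped_rows` attribute.
#'
#' @param efl Tibble of included losses (`pregnancy_id`, `dps_day`).
#' @param pool Character vector of full-term candidate ids.
#' @param zseries Prepared series for losses and candidates
#'   ([prepare_gee_series()]).
#' @param k Controls per loss.
#' @param seed Integer seed for control sampling.
#' @param thresholds Length-group thresholds.
#' @return A tibble of class `gw_gee_data`: `series_id` (grouping unit),
#'   `pregnancy_id`, `efl_anchor_id`, `day` (0..6), `category`,
#'   `length_threshold`, `z`.
#' @export
build_gee_dataset <- function(efl, pool, zseries, k = 5, seed = 1,
                              thresholds = c(14, 28, 40, 60)) {
  efl <- efl %>%
    dplyr::mutate(length_threshold =
                    assign_length_group(.data$dps_day, thresholds))
  rows_for <- function(id, anchor_id, L, category, threshold) {
    zseries %>%
      dplyr::filter(.data$pregnancy_id == id, .data$day >= L,
                    .data$day <= L + 6L) %>%
      dplyr::mutate(series_id = paste(anchor_id, id, sep = ":"),
                    pregnancy_id = id, efl_anchor_id = anchor_id,
                    day = .data$day - L, category = category,
                    length_threshold = threshold) %>%
      dplyr::select("series_id", "pregnancy_id", "efl_anchor_id", "day",
                    "category", "length_threshold", "z")
  }
  own <- purrr::map(seq_len(nrow(efl)), function(i) {
    rows_for(efl$pregnancy_id[i], efl$pregnancy_id[i], efl$dps_day[i],
             0, efl$length_threshold[i])
  }) %>% dplyr::bind_rows()
  kept_efl <- unique(own$series_id)
  if (length(kept_efl) < nrow(efl)) {
    rlang::inform(sprintf(
      "build_gee_dataset: %d losses excluded (no post-DPS days)",
      nrow(efl) - length(kept_efl)))
  }
  ctl_rows <- tibble::tibble()
  if (k > 0) {
    ctl <- sample_controls(efl, pool, zseries, k = k, seed = seed)
    ctl <- ctl %>%
      dplyr::left_join(efl %>% dplyr::select("pregnancy_id",
                                             "length_threshold"),
                       by = c("efl_id" = "pregnancy_id"))
    ctl_rows <- purrr::map(seq_len(nrow(ctl)), function(i) {
      rows_for(ctl$control_id[i], ctl$efl_id[i], ctl$dps_day[i],
               1, ctl$length_threshold[i])
    }) %>% dplyr::bind_rows()
  }
  out <- dplyr::bind_rows(own, ctl_rows) %>%
    dplyr::filter(!is.na(.data$z))
  expected <- 7L * length(kept_efl) * (1L + k)
  attr(out, "dropped_rows") <- expected - nrow(out)
  structure(out, class = c("gw_gee_data", class(tibble::tibble())))
}

#' Fit the three-way-interaction estimating-equations model
#'
#' Gaussian generalized estimating equations for
#' `z ~ day * category * length_threshold` (full factorial, the length
#' threshold entering as a numeric covariate), with each 7-day pregnancy
#' series as the grouping cluster and Liang-Zeger robust (sandwich) standard
#' errors.  The working correlation is independence by default (coefficients
#' then equal ordinary least squares); an exchangeable structure is
#' estimated by moment iteration when requested.
#'
#' With the category coding 0 = loss, 1 = full-term control, the `Day` main
#' effect is the post-loss slope of the losses, `Day:Category` measures how
#' much flatter the controls are, and the three-way interaction captures how
#' the loss-control slope gap changes with the pregnancy-length threshold.
#'
#' @param data A [build_gee_dataset()] result (or any data frame with
#'   columns `series_id`, `day`, `category`, `length_threshold`, `z`).
#' @param corstr `"independence"` or `"exchangeable"`.
#' @param maxit,tol Iteration controls for the exchangeable fit.
#' @return An object of class `gw_gee` with `tidy()` / `glance()` methods.
#' @export
fit_gee <- function(data, corstr = c("independence", "exchangeable"),
                    maxit = 25, tol = 1e-8) {
  corstr <- match.arg(corstr)
  gw_assert(dplyr::n_distinct(data$series_id) >= 2,
            "at least two grouping series are required")
  X <- stats::model.matrix(~ day * category * length_threshold, data = data)
  y <- data$z
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    rlang::abort(paste(
      "design matrix is rank deficient (e.g. a single length group makes",
      "the threshold collinear with the intercept); fit a reduced formula"))
  }
  id <- as.character(data$series_id)
  # order by cluster for blockwise algebra
  ord <- order(id)
  X <- X[ord, , drop = FALSE]
  y <- y[ord]
  id <- id[ord]
  blocks <- split(seq_along(id), id)
  p <- ncol(X)
  n_obs <- length(y)

  beta <- qr.coef(qr(X), y)
  alpha <- 0
  phi <- NA_real_
  if (corstr == "exchangeable") {
    for (it in seq_len(maxit)) {
      r <- y - X %*% beta
      phi <- sum(r^2) / (n_obs - p)
      if (phi <= 0 || !is.finite(phi) || phi < 1e-300) { alpha <- 0; break }
      num <- 0; den <- 0
      for (ix in blocks) {
        ri <- r[ix]
        ni <- length(ri)
        if (ni > 1) {
          num <- num + (sum(ri)^2 - sum(ri^2)) / 2
          den <- den + ni * (ni - 1) / 2
        }
      }
      alpha_new <- (num / phi) / max(den - p, 1)
      alpha_new <- max(min(alpha_new, 0.99), -0.5)
      A <- matrix(0, p, p)
      b <- numeric(p)
      for (ix in blocks) {
        Xi <- X[ix, , drop = FALSE]
        yi <- y[ix]
        ni <- length(ix)
        # V^-1 for (1-a)I + aJ via Sherman-Morrison
        f1 <- 1 / (1 - alpha_new)
        f2 <- alpha_new / ((1 - alpha_new) * (1 + (ni - 1) * alpha_new))
        Vi_inv_Xi <- f1 * Xi - f2 * matrix(colSums(Xi), ni, p, byrow = TRUE)
        Vi_inv_yi <- f1 * yi - f2 * sum(yi)
        A <- A + crossprod(Xi, Vi_inv_Xi)
        b <- b + crossprod(Xi, Vi_inv_yi)
      }
      beta_new <- solve(A, b)
      done <- max(abs(beta_new - beta)) < tol && abs(alpha_new - alpha) < tol
      beta <- drop(beta_new)
      alpha <- alpha_new
      if (done) break
    }
  }

  # sandwich covariance: B^-1 M B^-1
  r <- drop(y - X %*% beta)
  B <- matrix(0, p, p)
  M <- matrix(0, p, p)
  for (ix in blocks) {
    Xi <- X[ix, , drop = FALSE]
    ri <- r[ix]
    ni <- length(ix)
    if (corstr == "exchangeable" && alpha != 0) {
      f1 <- 1 / (1 - alpha)
      f2 <- alpha / ((1 - alpha) * (1 + (ni - 1) * alpha))
      Vi_inv_Xi <- f1 * Xi - f2 * matrix(colSums(Xi), ni, p, byrow = TRUE)
    } else {
      Vi_inv_Xi <- Xi
    }
    B <- B + crossprod(Xi, Vi_inv_Xi)
    u <- crossprod(Vi_inv_Xi, ri)
    M <- M + tcrossprod(u)
  }
  Binv <- solve(B)
  vcov <- Binv %*% M %*% Binv
  se <- unname(sqrt(pmax(diag(vcov), 0)))
  zstat <- ifelse(se > 0, beta / se, 0)
  pvals <- 2 * stats::pnorm(-abs(zstat))
  ci <- qnorm(0.975)
  labels <- c("(Intercept)" = "Intercept", "day" = "Day",
              "category" = "Category", "length_threshold" = "Length threshold",
              "day:category" = "Day:Category",
              "day:length_threshold" = "Day:Length threshold",
              "category:length_threshold" = "Category:Length threshold",
              "day:category:length_threshold" =
                "Day:Category:Length threshold")
  coefs <- tibble::tibble(
    term = unname(labels[colnames(X)]),
    estimate = unname(beta), std.error = se, statistic = unname(zstat),
    p.value = unname(pvals),
    conf.low = unname(beta) - ci * se, conf.high = unname(beta) + ci * se
  )
  structure(list(coefficients = coefs, corstr = corstr, alpha = alpha,
                 scale = if (is.na(phi)) sum(r^2) / (n_obs - p) else phi,
                 n_obs = n_obs, n_groups = length(blocks), vcov = vcov),
            class = "gw_gee")
}

#' @export
print.gw_gee <- function(x, ...) {
  cat("Gaussian GEE (", x$corstr, " working correlation), ",
      x$n_groups, " series / ", x$n_obs, " observations\n", sep = "")
  if (x$corstr == "exchangeable") {
    cat("estimated exchangeable correlation:", signif(x$alpha, 3), "\n")
  }
  print(as.data.frame(x$coefficients), digits = 3, row.names = FALSE)
  invisible(x)
}

#' Tidy a fitted estimating-equations model
#'
#' @param x A `gw_gee` object.
#' @param ... Unused.
#' @return A tibble with one row per model term (estimate, robust standard
#'   error, z statistic, p-value, 95\% confidence bounds).
#' @method tidy gw_gee
#' @export
tidy.gw_gee <- function(x, ...) {
  x$coefficients
}

#' One-row model summary of a fitted estimating-equations model
#'
#' @param x A `gw_gee` object.
#' @param ... Unused.
#' @return A one-row tibble: working-correlation structure, estimated
#'   exchangeable correlation, residual scale, observation and cluster
#'   counts.
#' @method glance gw_gee
#' @export
glance.gw_gee <- function(x, ...) {
  tibble::tibble(corstr = x$corstr, alpha = x$alpha, scale = x$scale,
                 n_obs = x$n_obs, n_groups = x$n_groups)
}
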