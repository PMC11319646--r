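#' Daily 4-dimensional multimodal points
#'
#' Builds, per pregnancy and aligned day, the 4-vector of z-scored daily
#' means of the four most complete series: nightly peak temperature, nightly
#' trough temperature, nightly peak heart rate and nightly peak heart-rate
#' variability.  A day is usable only when all four components are present;
#' pregnancies missing a component series entirely are excluded with a
#' message.
#'
#' @param zaligned Z-scored DKP-aligned long tibble.
#' @return Tibble (`pregnancy_id`, `day`, `temp_peak`, `temp_trough`, `hr`,
#'   `hrv`, `usable`).
#' @export
daily_points <- function(zaligned) {
  comp <- gw_series_map() %>% dplyr::filter(.data$series != "rr",
                                            .data$series != "met")
  pts <- zaligned %>%
    dplyr::inner_join(comp, by = c("modality", "statistic", "window")) %>%
    dplyr::select("pregnancy_id", "day", "series", "value") %>%
    tidyr::pivot_wider(names_from = "series", values_from = "value")
  for (s in comp$series) {
    if (!s %in% names(pts)) pts[[s]] <- NA_real_
  }
  missing_series <- pts %>%
    dplyr::group_by(.data$pregnancy_id) %>%
    dplyr::summarise(dplyr::across(dplyr::all_of(comp$series),
                                   ~ all(is.na(.x))), .groups = "drop") %>%
    dplyr::filter(dplyr::if_any(dplyr::all_of(comp$series))) %>%
    dplyr::pull("pregnancy_id")
  if (length(missing_series) > 0) {
    rlang::inform(sprintf(
      "daily_points: %d pregnancies lack a component series and are excluded",
      length(missing_series)))
    pts <- pts %>% dplyr::filter(!.data$pregnancy_id %in% missing_series)
  }
  pts %>%
    dplyr::mutate(usable = !is.na(.data$temp_peak) &
                    !is.na(.data$temp_trough) & !is.na(.data$hr) &
                    !is.na(.data$hrv)) %>%
    dplyr::arrange(.data$pregnancy_id, .data$day)
}

#' Per-day reference profile (componentwise mean, optional leave-one-out)
#'
#' The componentwise mean 4-vector over the reference group's usable days,
#' excluding `leave_out` when given (used so that a reference-group member
#' is compared against the mean of all *other* members).
#'
#' @param points Output of [daily_points()] restricted to the reference
#'   group.
#' @param leave_out Optional pregnancy id to exclude.
#' @return Tibble (`day`, `temp_peak`, `temp_trough`, `hr`, `hrv`,
#'   `n_ref`); days with no contributor are omitted.
#' @export
reference_profile <- function(points, leave_out = NULL) {
  ref <- points %>% dplyr::filter(.data$usable)
  if (!is.null(leave_out)) {
    if (dplyr::n_distinct(points$pregnancy_id) < 2) {
      rlang::abort("leave-one-out reference requires a group of >= 2")
    }
    ref <- ref %>% dplyr::filter(.data$pregnancy_id != leave_out)
  }
  ref %>%
    dplyr::group_by(.data$day) %>%
    dplyr::summarise(dplyr::across(dplyr::all_of(c("temp_peak",
                                                   "temp_trough", "hr",
                                                   "hrv")), mean),
                     n_ref = dplyr::n(), .groups = "drop")
}

#' Daily and cumulative multimodal distance to a reference
#'
#' Euclidean (L2) distance between one pregnancy's daily 4-vector and the
#' reference profile, accumulated over aligned days `day_range[1]` through
#' `day_range[2]` (default -28, four weeks before the pregnancy became
#' known, through day 252, 40 weeks).  Days without a usable point or
#' reference contribute zero and carry the cumulative value forward, so the
#' cumulative series is nondecreasing.
#'
#' @param points [daily_points()] rows for a single pregnancy.
#' @param reference A [reference_profile()].
#' @param day_range Inclusive aligned-day range.
#' @return Tibble (`pregnancy_id`, `day`, `distance`, `cumulative`).
#' @export
distance_series <- function(points, reference, day_range = c(-28, 252)) {
  gw_assert(dplyr::n_distinct(points$pregnancy_id) <= 1,
            "`points` must contain a single pregnancy")
  grid <- tibble::tibble(day = seq(day_range[1], day_range[2]))
  comp <- c("temp_peak", "temp_trough", "hr", "hrv")
  joined <- grid %>%
    dplyr::left_join(points %>% dplyr::filter(.data$usable) %>%
                       dplyr::select("day", dplyr::all_of(comp)),
                     by = "day") %>%
    dplyr::left_join(reference %>%
                       dplyr::select("day", dplyr::all_of(comp)) %>%
                       dplyr::rename_with(~ paste0(.x, "_ref"),
                                          dplyr::all_of(comp)),
                     by = "day")
  if (!any(stats::complete.cases(joined[-1]))) {
    rlang::warn("distance_series: no shared usable days with the reference")
  }
  d2 <- (joined$temp_peak - joined$temp_peak_ref)^2 +
    (joined$temp_trough - joined$temp_trough_ref)^2 +
    (joined$hr - joined$hr_ref)^2 + (joined$hrv - joined$hrv_ref)^2
  dist <- ifelse(is.na(d2), 0, sqrt(d2))
  tibble::tibble(pregnancy_id = points$pregnancy_id[1] %||% NA_character_,
                 day = grid$day, distance = dist,
                 cumulative = cumsum(dist))
}

#' Cumulative multimodal distance for two groups
#'
#' For every member of the reference group (by default the under-35
#' pregnancies) the distance is taken to the leave-one-out mean of the rest
#' of that group; for every member of the comparison group, to the full
#' reference-group mean.
#'
#' @param points Output of [daily_points()] for all pregnancies.
#' @param records Data frame with `pregnancy_id` and a grouping column.
#' @param group_col Name of the grouping column (default `"age_group"`;
#'   computed from `age_bin` when absent).
#' @param reference_group Level of `group_col` used as reference.
#' @param day_range Inclusive aligned-day range.
#' @return A tibble of class `gw_distance` (`pregnancy_id`, `group`, `day`,
#'   `distance`, `cumulative`).
#' @export
cumulative_distance <- function(points, records, group_col = "age_group",
                                reference_group = "<35",
                                day_range = c(-28, 252)) {
  records <- tibble::as_tibble(records)
  if (!group_col %in% names(records) && "age_bin" %in% names(records)) {
    records[[group_col]] <- age_group(records$age_bin)
  }
  gw_assert(group_col %in% names(records),
            paste0("records lack grouping column `", group_col, "`"))
  grp <- records %>%
    dplyr::select("pregnancy_id", group = dplyr::all_of(group_col))
  pts <- points %>% dplyr::inner_join(grp, by = "pregnancy_id")
  ref_pts <- pts %>% dplyr::filter(.data$group == reference_group)
  ref_full <- reference_profile(ref_pts)
  ids <- pts %>% dplyr::distinct(.data$pregnancy_id, .data$group)
  out <- purrr::map(seq_len(nrow(ids)), function(i) {
    id <- ids$pregnancy_id[i]
    ref <- if (ids$group[i] == reference_group) {
      reference_profile(ref_pts, leave_out = id)
    } else {
      ref_full
    }
    distance_series(pts %>% dplyr::filter(.data$pregnancy_id == id),
                    ref, day_range) %>%
      dplyr::mutate(group = ids$group[i], .after = "pregnancy_id")
  }) %>% dplyr::bind_rows()
  structure(out, class = c("gw_distance", class(tibble::tibble())))
}

#' Compare cumulative-distance endpoints between groups
#'
#' Kruskal-Wallis rank test (with tie correction) on the cumulative
#' multimodal distance at the final day of the analysis window (40 weeks,
#' day 252, by default).
#'
#' @param distances A [cumulative_distance()] result.
#' @param at_day Day whose cumulative value is compared (default the series
#'   maximum).
#' @return One-row tibble: `H`, `df`, `p`, `n_groups`, `sizes` (list of
#'   per-group sizes).
#' @export
compare_final_distance <- function(distances, at_day = NULL) {
  at_day <- at_day %||% max(distances$day)
  ends <- distances %>%
    dplyr::filter(.data$day == at_day) %>%
    dplyr::distinct(.data$pregnancy_id, .data$group, .data$cumulative)
  gw_assert(dplyr::n_distinct(ends$group) >= 2,
            "at least two groups are required")
  gw_assert(all(table(ends$group) >= 2),
            "each group needs >= 2 members")
  ht <- stats::kruskal.test(ends$cumulative, factor(ends$group))
  tibble::tibble(H = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value, n_groups = dplyr::n_distinct(ends$group),
                 sizes = list(table(ends$group)))
}
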