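#' Classify pregnancy outcomes from survey records
#'
#' Derives `gestation_days = (dps - dkp) + 28` (conception modelled 28 days
#' before the pregnancy became known) and classifies delivered pregnancies
#' as full-term (`gestation_days >= 259`, i.e. 37 weeks) or preterm.
#' Early-fetal-loss subtypes and the partner-report / out-of-window survey
#' labels pass through unchanged.  Records missing an anchor date get
#' `outcome_class = NA` and are excluded downstream.
#'
#' @param survey Survey tibble with columns `pregnancy_id`, `dkp`, `dps`,
#'   `outcome` (and any extra columns, which are preserved).
#' @return The survey tibble with `gestation_days` and `outcome_class`
#'   columns added.
#' @export
classify_outcome <- function(survey) {
  survey %>%
    dplyr::mutate(
      gestation_days = as.integer(.data$dps - .data$dkp) + 28L,
      outcome_class = dplyr::case_when(
        is.na(.data$dkp) | is.na(.data$dps) ~ NA_character_,
        .data$outcome %in% c("partner_report", "out_of_window") ~
          .data$outcome,
        startsWith(.data$outcome, "efl") ~ .data$outcome,
        .data$gestation_days >= 259L ~ "full_term",
        TRUE ~ "preterm"
      )
    )
}

#' Per-trimester temperature completeness
#'
#' For every pregnancy, the fraction of days inside each trimester window
#' with a nightly peak-temperature aggregate.  Eligibility for the full-term
#' arm requires all of trimesters 1-3 at or above `threshold`.
#'
#' @param daily Long daily-aggregate tibble.
#' @param survey Survey tibble with `pregnancy_id`, `dkp`.
#' @param scheme An [alignment_scheme()].
#' @param threshold Minimum fraction of days with data (default 0.40).
#' @return Tibble with one row per pregnancy: per-trimester day counts
#'   (`days_*`), fractions (`frac_*`) and `eligible`.
#' @export
trimester_completeness <- function(daily, survey,
                                   scheme = alignment_scheme(),
                                   threshold = 0.40) {
  win <- scheme$trimester_windows %>%
    dplyr::filter(.data$trimester %in% c("t1", "t2", "t3"))
  if (nrow(survey) == 0) {
    return(tibble::tibble(pregnancy_id = character(), days_t1 = integer(),
                          days_t2 = integer(), days_t3 = integer(),
                          frac_t1 = double(), frac_t2 = double(),
                          frac_t3 = double(), eligible = logical()))
  }
  temp_days <- daily %>%
    dplyr::filter(.data$modality == "temperature",
                  .data$statistic == "peak", .data$window == "nightly") %>%
    dplyr::inner_join(survey %>% dplyr::select("pregnancy_id", "dkp"),
                      by = "pregnancy_id") %>%
    dplyr::mutate(day = as.integer(.data$date - .data$dkp)) %>%
    dplyr::distinct(.data$pregnancy_id, .data$day)
  counts <- purrr::pmap(win, function(trimester, start, end) {
    temp_days %>%
      dplyr::filter(.data$day >= start, .data$day < end) %>%
      dplyr::count(.data$pregnancy_id) %>%
      dplyr::mutate(trimester = trimester, frac = .data$n / (end - start))
  }) %>% dplyr::bind_rows()
  survey %>%
    dplyr::select("pregnancy_id") %>%
    tidyr::crossing(trimester = win$trimester) %>%
    dplyr::left_join(counts, by = c("pregnancy_id", "trimester")) %>%
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L),
                  frac = dplyr::coalesce(.data$frac, 0)) %>%
    tidyr::pivot_wider(names_from = "trimester",
                       values_from = c("n", "frac"),
                       names_glue = "{.value}_{trimester}") %>%
    dplyr::rename(days_t1 = "n_t1", days_t2 = "n_t2", days_t3 = "n_t3") %>%
    dplyr::mutate(eligible = .data$frac_t1 >= threshold &
                    .data$frac_t2 >= threshold & .data$frac_t3 >= threshold)
}

#' Build the analysis cohort with an exclusion ledger
#'
#' Applies the eligibility filters in narrative order and records exactly one
#' exclusion reason per removed pregnancy.  Delivered arm: partner-report and
#' out-of-window survey labels, then the three-trimester temperature
#' completeness filter (`sparse_trimester`), then the other-reason sparse
#' flag carried on the survey (`sparse_other`), then preterm gestation.  EFL
#' arm: failure-to-implant outcome, low first-trimester completeness, then
#' the low prior-completeness flag.  Multiple pregnancies from one
#' participant are retained as independent analysis units.
#'
#' @param survey Survey tibble.
#' @param daily Long daily-aggregate tibble.
#' @param scheme An [alignment_scheme()].
#' @param threshold Completeness threshold (default 0.40).
#' @return A list of class `gw_cohort`: `records` (survey + classification +
#'   completeness + `included` + `exclusion_reason`), `ledger` (counts per
#'   reason and arm), and `orphans` (pregnancy ids present in `daily` but not
#'   the survey).
#' @export
build_cohort <- function(survey, daily, scheme = alignment_scheme(),
                         threshold = 0.40) {
  orphans <- setdiff(unique(daily$pregnancy_id), survey$pregnancy_id)
  if (length(orphans) > 0) {
    rlang::warn(sprintf("%d pregnancies have data but no survey row; excluded",
                        length(orphans)))
  }
  records <- classify_outcome(survey) %>%
    dplyr::left_join(trimester_completeness(daily, survey, scheme, threshold),
                     by = "pregnancy_id")
  flag <- if ("sparse_flag" %in% names(records)) records$sparse_flag
          else rep("none", nrow(records))
  records <- records %>%
    dplyr::mutate(
      arm = dplyr::case_when(
        .data$outcome_class %in% c("full_term", "preterm") ~ "delivered",
        startsWith(dplyr::coalesce(.data$outcome_class, ""), "efl") ~ "efl",
        TRUE ~ "other"
      ),
      exclusion_reason = dplyr::case_when(
        is.na(.data$outcome_class) ~ "missing_dates",
        .data$outcome_class == "partner_report" ~ "partner_report",
        .data$outcome_class == "out_of_window" ~ "out_of_window",
        .data$arm == "delivered" & !.data$eligible ~ "sparse_trimester",
        .data$arm == "delivered" & flag == "sparse_other" ~ "sparse_other",
        .data$outcome_class == "preterm" ~ "preterm",
        .data$outcome_class == "efl_failure_to_implant" ~
          "failure_to_implant",
        .data$arm == "efl" & .data$frac_t1 < threshold ~
          "low_first_trimester",
        .data$arm == "efl" & flag == "low_prior_completeness" ~
          "low_prior_completeness",
        TRUE ~ "none"
      ),
      included = .data$exclusion_reason == "none"
    )
  ledger <- records %>%
    dplyr::count(.data$arm, .data$exclusion_reason, .data$included,
                 name = "n") %>%
    dplyr::arrange(.data$arm, dplyr::desc(.data$n))
  structure(list(records = records, ledger = ledger, orphans = orphans),
            class = "gw_cohort")
}

#' @export
print.gw_cohort <- function(x, ...) {
  cat("<gw_cohort>", sum(x$records$included), "included /",
      nrow(x$records), "survey pregnancies\n")
  print(x$ledger, n = Inf)
  invisible(x)
}

#' Align daily aggregates to pregnancy-relative day indices
#'
#' Re-indexes each pregnancy's daily values to integer days relative to an
#' anchor date: the day the pregnancy became known (`"dkp"`, used for
#' trajectory analyses) or the day it stopped (`"dps"`, used for
#' peridelivery and loss analyses).  Day 0 is the anchor; missing days are
#' simply absent.
#'
#' @param daily Long daily-aggregate tibble.
#' @param records Data frame with `pregnancy_id` and the anchor date columns
#'   (`dkp`, `dps`); typically `cohort$records` filtered to `included`.
#' @param anchor `"dkp"` or `"dps"`.
#' @return Long aligned tibble (`pregnancy_id`, `day`, `window`, `modality`,
#'   `statistic`, `value`).
#' @export
align_series <- function(daily, records, anchor = c("dkp", "dps")) {
  anchor <- match.arg(anchor)
  anchors <- records %>%
    dplyr::select("pregnancy_id", anchor_date = dplyr::all_of(anchor))
  if (any(is.na(anchors$anchor_date))) {
    bad <- anchors$pregnancy_id[is.na(anchors$anchor_date)]
    rlang::abort(paste0("anchor date `", anchor, "` missing for pregnancy ",
                        paste(bad, collapse = ", ")))
  }
  daily %>%
    dplyr::inner_join(anchors, by = "pregnancy_id") %>%
    dplyr::mutate(day = as.integer(.data$date - .data$anchor_date)) %>%
    dplyr::select("pregnancy_id", "day", "window", "modality", "statistic",
                  "value")
}

#' Locate the last pre-pregnancy temperature cycle trough
#'
#' Diagnostic consistency check of the alignment convention: the argmin of a
#' 5-day centered rolling mean of the nightly peak-temperature series over
#' days `[-45, 0)`.  In a well-aligned pregnancy this sits near day -28
#' (conception, one cycle before the pregnancy became known).  The result is
#' reported only -- it is never used to re-anchor.
#'
#' @param aligned DKP-aligned long tibble (any subset containing the nightly
#'   peak-temperature rows).
#' @param min_days Minimum number of observed days in `[-45, 0)` for the
#'   diagnostic to be emitted (default 35).
#' @return Tibble (`pregnancy_id`, `trough_day`, `low_confidence`); rows are
#'   omitted for pregnancies with insufficient pre-pregnancy data.
#' @export
detect_cycle_trough <- function(aligned, min_days = 35) {
  aligned %>%
    dplyr::filter(.data$modality == "temperature",
                  .data$statistic == "peak", .data$window == "nightly",
                  .data$day >= -45, .data$day < 0) %>%
    dplyr::group_by(.data$pregnancy_id) %>%
    dplyr::group_modify(function(df, key) {
      if (nrow(df) < min_days) return(tibble::tibble())
      grid <- seq(min(df$day), max(df$day))
      v <- rep(NA_real_, length(grid))
      v[match(df$day, grid)] <- df$value
      sm <- zoo::rollapply(v, width = 5, partial = TRUE,
                           FUN = function(w) mean(w, na.rm = TRUE),
                           align = "center")
      at <- which.min(sm)
      tibble::tibble(trough_day = grid[at],
                     low_confidence = at == 1L || at == length(grid))
    }) %>%
    dplyr::ungroup()
}
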