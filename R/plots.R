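#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a population trajectory profile
#'
#' Median line with the quantile band and the bootstrap confidence interval
#' of the median, one panel per series.
#'
#' @param object A [population_profile()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gw_profile
#' @export
autoplot.gw_profile <- function(object, ...) {
  df <- object %>%
    dplyr::mutate(series = paste(.data$modality, .data$statistic,
                                 .data$window))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$day)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$q_lo, ymax = .data$q_hi),
                         fill = "steelblue", alpha = 0.25, na.rm = TRUE) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_lo,
                                      ymax = .data$ci_hi),
                         fill = "steelblue", alpha = 0.45, na.rm = TRUE) +
    ggplot2::geom_line(ggplot2::aes(y = .data$median)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "darkgreen") +
    ggplot2::facet_wrap(~series, scales = "free_y") +
    ggplot2::labs(x = "day relative to anchor", y = "value")
}

#' Plot cumulative multimodal distances by group
#'
#' One cumulative-distance trace per pregnancy, coloured by group.
#'
#' @param object A [cumulative_distance()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gw_distance
#' @export
autoplot.gw_distance <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$day, y = .data$cumulative,
                               group = .data$pregnancy_id,
                               colour = .data$group)) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::labs(x = "day relative to pregnancy awareness",
                  y = "cumulative multimodal distance")
}

#' Boxplots of per-pregnancy trimester means
#'
#' The trimester-profile view: one box per trimester, faceted by series,
#' the display behind the adjacent-trimester rank tests.
#'
#' @param tmeans A [trimester_means()] result.
#' @return A ggplot object.
#' @export
plot_trimester_box <- function(tmeans) {
  df <- tmeans %>%
    dplyr::mutate(series = paste(.data$modality, .data$statistic,
                                 .data$window),
                  trimester = factor(.data$trimester,
                                     levels = c("t-1", "t1", "t2", "t3",
                                                "t4")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$trimester, y = .data$mean)) +
    ggplot2::geom_boxplot(fill = "steelblue", alpha = 0.4) +
    ggplot2::facet_wrap(~series, scales = "free_y") +
    ggplot2::labs(x = "trimester", y = "per-pregnancy mean")
}

#' Coefficient plot for a fitted estimating-equations model
#'
#' Point estimates with 95\% confidence bars, excluding the intercept.
#'
#' @param fit A [fit_gee()] result.
#' @return A ggplot object.
#' @export
plot_gee_coefficients <- function(fit) {
  df <- tidy(fit) %>% dplyr::filter(.data$term != "Intercept")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::labs(x = "coefficient (z-scored temperature units)", y = NULL)
}
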