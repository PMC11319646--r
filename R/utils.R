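# Internal helpers shared across modules.

# Interpolated quantile of order statistics (R type 7), the fixed convention
# for every quantile in the package.
gw_quantile <- function(x, p) {
  unname(stats::quantile(x, probs = p, type = 7, names = FALSE, na.rm = FALSE))
}

# Mean of the sample values whose midpoint rank (i - 0.5)/n falls inside
# `band`; falls back to the interpolated quantile at the band midpoint when
# no order statistic lands in the band (small n).
gw_band_mean <- function(x, band, definition = c("band_mean", "endpoint_mean")) {
  definition <- match.arg(definition)
  if (length(x) == 0L) return(NA_real_)
  if (definition == "endpoint_mean") {
    return(mean(gw_quantile(x, band)))
  }
  s <- sort(x)
  mid <- (seq_along(s) - 0.5) / length(s)
  sel <- mid >= band[1] & mid <= band[2]
  if (any(sel)) mean(s[sel]) else gw_quantile(x, mean(band))
}

# Piecewise-linear trajectory evaluated at `day`, constant beyond end knots.
gw_piecewise <- function(day, knots, values) {
  stats::approx(knots, values, xout = day, rule = 2, ties = "ordered")$y
}

# Deterministic child seeds (< 2^31) derived from a parent seed.
gw_child_seeds <- function(seed, n) {
  withr::with_seed(seed, sample.int(2000000000L, n))
}

# Significance annotation ladder with Bonferroni correction for
# `m` comparisons applied to the conventional 0.05/0.01/0.001/1e-4 rungs.
gw_annotate_p <- function(p, m = 4) {
  cuts <- c(0.05, 0.01, 0.001, 1e-4) / m
  dplyr::case_when(
    is.na(p) ~ NA_character_,
    p <= cuts[4] ~ "****",
    p <= cuts[3] ~ "***",
    p <= cuts[2] ~ "**",
    p <= cuts[1] ~ "*",
    TRUE ~ "ns"
  )
}

gw_assert <- function(ok, msg) {
  if (!isTRUE(ok)) rlang::abort(msg)
  invisible(TRUE)
}

# Trailing rolling mean over *calendar* days: for each observed day d the
# mean of the values observed in (d - window + 1, ..., d).  Missing days
# contribute nothing; every observed day keeps a value (>= 1 observation:
# itself).  Used for the 7-day trajectory smoothing and the 3-day smoothing
# ahead of the estimating-equation fit.
gw_roll_days <- function(day, value, window) {
  if (window == 1L || length(day) <= 1L) return(value)
  grid <- seq(min(day), max(day))
  v <- rep(NA_real_, length(grid))
  v[match(day, grid)] <- value
  sm <- zoo::rollapplyr(v, width = window, partial = TRUE,
                        FUN = function(w) mean(w, na.rm = TRUE))
  sm[match(day, grid)]
}
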