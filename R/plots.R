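# ggplot2 views of the main result types.

#' Plot per-site scaled cover trajectories
#'
#' @param cover A cover-series tibble from [build_cover_series()].
#' @param max_sites Plot at most this many sites (first in sort order).
#' @return A ggplot object: scaled cover vs year, one panel line per
#'   site, filtered years marked.
#' @export
plot_cover_series <- function(cover, max_sites = 12) {
  check_columns(cover, c("site_id", "year", "scaled_cover", "filtered"),
                "cover")
  keep <- head(sort(unique(cover$site_id)), max_sites)
  d <- filter(cover, .data$site_id %in% keep)
  ggplot(d, aes(x = .data$year, y = .data$scaled_cover)) +
    geom_line(colour = "seagreen4") +
    geom_point(aes(shape = .data$filtered), size = 1.6) +
    scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 4)) +
    facet_wrap(~site_id) +
    labs(x = "Year", y = "Scaled density-weighted cover",
         shape = "Filtered") +
    theme_minimal()
}

#' Plot deviance ratios around the long-term mean
#'
#' @param trend Output of [deviance_ratio()] (optionally with a
#'   `species` column).
#' @return A ggplot object with the 1.0 reference line.
#' @export
plot_deviance <- function(trend) {
  check_columns(trend, c("year", "ratio"), "trend")
  p <- ggplot(trend, aes(x = .data$year, y = .data$ratio)) +
    geom_hline(yintercept = 1, linetype = "dashed", colour = "red3") +
    geom_line() +
    geom_point() +
    labs(x = "Year", y = "Cover / long-term mean cover") +
    theme_minimal()
  if ("species" %in% names(trend)) {
    p <- p + aes(colour = .data$species) + labs(colour = "Species")
  }
  p
}

#' Coefficient plot of a mixed-model fit
#'
#' @param object A `sav_lmm` fit.
#' @param ... Unused.
#' @return A ggplot dot-whisker plot of fixed-effect estimates with
#'   approximate 95% intervals.
#' @method autoplot sav_lmm
#' @export
autoplot.sav_lmm <- function(object, ...) {
  d <- tidy(object) |>
    filter(.data$term != "(Intercept)") |>
    mutate(lo = .data$estimate - 1.96 * .data$std.error,
           hi = .data$estimate + 1.96 * .data$std.error)
  ggplot(d, aes(x = .data$estimate, y = .data$term)) +
    geom_vline(xintercept = 0, linetype = "dashed") +
    geom_errorbarh(aes(xmin = .data$lo, xmax = .data$hi), height = 0.15) +
    geom_point(size = 2) +
    labs(x = "Estimate", y = NULL) +
    theme_minimal()
}

#' Standardized path-coefficient plot of a piecewise SEM
#'
#' @param object A `sav_sem` fit.
#' @param alpha Significance level separating solid from faded paths.
#' @param ... Unused.
#' @return A ggplot object: standardized coefficients per equation,
#'   positive paths in black, negative in red, faded when
#'   non-significant.
#' @method autoplot sav_sem
#' @export
autoplot.sav_sem <- function(object, alpha = 0.05, ...) {
  d <- tidy(object) |>
    filter(.data$term != "(Intercept)") |>
    mutate(sign = ifelse(.data$std_estimate >= 0, "positive", "negative"),
           significant = .data$p.value <= alpha)
  ggplot(d, aes(x = .data$std_estimate, y = .data$term,
                colour = .data$sign, alpha = .data$significant)) +
    geom_vline(xintercept = 0, linetype = "dashed") +
    geom_point(size = 2.5) +
    scale_colour_manual(values = c(positive = "black", negative = "red3")) +
    scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.35)) +
    facet_wrap(~equation, scales = "free_y") +
    labs(x = "Standardized path coefficient", y = NULL,
         colour = "Direction", alpha = sprintf("P <= %.2f", alpha)) +
    theme_minimal()
}

#' Flow-regression scatter plot
#'
#' @param object A `sav_flowfit`.
#' @param ... Unused.
#' @return A ggplot object: areal change vs (log) discharge with the
#'   fitted line.
#' @method autoplot sav_flowfit
#' @export
autoplot.sav_flowfit <- function(object, ...) {
  ggplot(object$data, aes(x = .data$x, y = .data$y)) +
    geom_point() +
    geom_abline(intercept = object$intercept, slope = object$slope,
                colour = "steelblue") +
    labs(x = ifelse(object$log, "log mean discharge", "Mean discharge"),
         y = "Annual areal change (ha)",
         subtitle = sprintf("R² = %.3f, F(%d,%d) = %.2f, P = %.3g",
                            object$r2, object$df[1], object$df[2],
                            object$f_stat, object$p_value)) +
    theme_minimal()
}
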