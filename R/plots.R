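#' Plot microstate template maps
#'
#' Schematic topographic maps: each class's template values drawn at the
#' electrode positions projected onto the 2-D scalp plane (azimuthal
#' projection), faceted by class.
#'
#' @param object a [microstate_model].
#' @param montage the montage giving electrode positions; defaults to the
#'   built-in 10-10 montage matched by channel label.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.microstate_model <- function(object, montage = NULL, ...) {
  ch <- colnames(object$maps)
  montage <- montage %||% montage_for_labels(ch)
  p <- montage_positions(montage)[ch, , drop = FALSE]
  # azimuthal equidistant projection from the vertex
  incl <- acos(pmin(pmax(p[, 3L], -1), 1))
  az <- atan2(p[, 2L], p[, 1L])
  px <- incl * cos(az)
  py <- incl * sin(az)
  d <- tidy(object)
  d$px <- px[match(d$channel, ch)]
  d$py <- py[match(d$channel, ch)]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$px, y = .data$py,
                                  colour = .data$value)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::facet_wrap(~class, labeller = ggplot2::label_both) +
    ggplot2::scale_colour_gradient2(low = "#2166ac", mid = "white",
                                    high = "#b2182b") +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::labs(colour = "a.u.")
}

#' Plot an autoinformation curve
#'
#' @param object a [seq_dynamics] object.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.seq_dynamics <- function(object, ...) {
  g <- ggplot2::ggplot(object$aif,
                       ggplot2::aes(x = .data$lag_ms, y = .data$aif)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "lag (ms)", y = "autoinformation (bits)")
  if (!is.na(object$first_peak_latency_ms)) {
    g <- g + ggplot2::geom_vline(xintercept = object$first_peak_latency_ms,
                                 linetype = "dashed", colour = "#b2182b")
  }
  g
}

#' Plot DFA fluctuations
#'
#' Log-log fluctuation curve from [dfa_hurst()] with the fitted scaling
#' range highlighted.
#'
#' @param dfa result list of [dfa_hurst()].
#' @return a ggplot object.
#' @export
plot_dfa <- function(dfa) {
  ggplot2::ggplot(dfa$fluctuations,
                  ggplot2::aes(x = .data$size, y = .data$fluctuation,
                               colour = .data$in_fit)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "window size (samples)", y = "fluctuation",
                  colour = "in fit",
                  subtitle = sprintf("H = %.3f (R^2 = %.3f)", dfa$hurst,
                                     dfa$r_squared))
}

#' Plot cohort sequence dynamics by condition
#'
#' @param object a `cohort_report`.
#' @param which "entropy_rate" or "hurst_mean".
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.cohort_report <- function(object,
                                   which = c("entropy_rate", "hurst_mean"),
                                   ...) {
  which <- match.arg(which)
  d <- object$dynamics_condition
  ggplot2::ggplot(d, ggplot2::aes(x = .data$condition,
                                  y = .data[[which]])) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.6) +
    ggplot2::labs(x = NULL,
                  y = if (which == "entropy_rate")
                    "entropy rate (bits/sample)" else "mean Hurst exponent")
}

#' Plot region-aggregated task-related power
#'
#' @param trp_regions tibble from [aggregate_regions()].
#' @param band band to show.
#' @return a ggplot object.
#' @export
plot_trp <- function(trp_regions, band = "alpha") {
  d <- trp_regions[trp_regions$band == band, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$condition, y = .data$trp,
                                  fill = .data$hemisphere)) +
    ggplot2::stat_summary(fun = mean, geom = "col",
                          position = ggplot2::position_dodge()) +
    ggplot2::facet_wrap(~region) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::labs(y = sprintf("TRP (%s band, log10 units)", band), x = NULL)
}
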