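#' Plot a fitted calibration curve over the titration data
#'
#' @param object A `calibration_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot calibration_fit
#' @export
autoplot.calibration_fit <- function(object, ...) {
  dat <- object$data
  grid <- tibble(
    free_ca_um = exp(seq(log(max(min(dat$free_ca_um[dat$free_ca_um > 0]),
                                  1e-3)),
                         log(max(dat$free_ca_um)), length.out = 200))
  )
  grid$ratio <- ca_to_ratio(grid$free_ca_um * 1000, object$curve)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$free_ca_um, y = .data$ratio)) +
    ggplot2::geom_line(data = grid, color = "grey40") +
    ggplot2::geom_point(color = "#2166ac") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression("free " * Ca^{2 + "+"} * " (uM)"),
                  y = "YFP/CFP ratio",
                  title = "Hill-sigmoid indicator calibration") +
    ggplot2::theme_minimal()
}

#' Plot a ratio frequency distribution
#'
#' @param object A `ratio_histogram` from [ratio_histogram()]; the overload
#'   threshold, when annotated, is drawn as a dashed line.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ratio_histogram
#' @export
autoplot.ratio_histogram <- function(object, ...) {
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$bin_mid, y = .data$frequency)) +
    ggplot2::geom_col(width = object$bin_hi[1] - object$bin_lo[1],
                      fill = "#2166ac", alpha = 0.8) +
    ggplot2::labs(x = "YFP/CFP ratio", y = "frequency") +
    ggplot2::theme_minimal()
  thr <- attr(object, "threshold")
  if (!is.null(thr))
    p <- p + ggplot2::geom_vline(xintercept = thr, linetype = "dashed")
  p
}

#' Plot overload probability against distance to the nearest plaque
#'
#' @param object A `distance_bin_table` from [overload_vs_distance()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot distance_bin_table
#' @export
autoplot.distance_bin_table <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = (.data$bin_lo + .data$bin_hi) / 2,
                               y = .data$overload_pct)) +
    ggplot2::geom_col(fill = "#b2182b", alpha = 0.8,
                      width = object$bin_hi[1] - object$bin_lo[1]) +
    ggplot2::labs(x = "distance to plaque edge (um)",
                  y = "overloaded mitochondria (%)") +
    ggplot2::theme_minimal()
}

#' Plot least-squares group means from a mixed-model fit
#'
#' @param object A `cohort_lmm` from [fit_group_lmm()].
#' @param ... Unused.
#' @return A ggplot of LS means with standard-error bars.
#' @method autoplot cohort_lmm
#' @export
autoplot.cohort_lmm <- function(object, ...) {
  m <- object$means
  ggplot2::ggplot(m, ggplot2::aes(x = .data$group, y = .data$emmean)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$emmean - .data$SE,
                                        ymax = .data$emmean + .data$SE),
                           width = 0.15) +
    ggplot2::labs(x = NULL, y = object$response,
                  title = "Least-squares means (mouse random effect)") +
    ggplot2::theme_minimal()
}
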