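#' Scatter plot of fusion-model versus reference voxel pO2
#'
#' MPO2 against GPO2 for the valid voxels, with the identity line and
#' the OLS fit.
#'
#' @param object An `oxygen_maps`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.oxygen_maps <- function(object, ...) {
  v <- dplyr::filter(object$voxels, .data$valid, is.finite(.data$gpo2),
                     is.finite(.data$mpo2))
  ggplot2::ggplot(v, ggplot2::aes(x = .data$gpo2, y = .data$mpo2)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "red", linewidth = 0.6) +
    ggplot2::labs(x = "GPO2 (mmHg, reference)", y = "MPO2 (mmHg, fusion model)",
                  title = sprintf("Voxel size %g µm", object$grid$L)) +
    ggplot2::theme_minimal()
}

#' Plot a sensitivity scan
#'
#' Percent deviation of the mean MPO2 per input and scale factor.
#'
#' @param object A `sensitivity_table` from [sensitivity_scan()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sensitivity_table <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = factor(100 * (.data$factor - 1)),
                               y = .data$percent_deviation,
                               fill = .data$input)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "Input change (%)", y = "MPO2 deviation (%)",
                  fill = "Input") +
    ggplot2::theme_minimal()
}

#' Plot an error-propagation result
#'
#' Replicate mean MPO2 (with SD error bars) against the reference GPO2.
#'
#' @param object An `error_propagation`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.error_propagation <- function(object, ...) {
  ggplot2::ggplot(object$voxels,
                  ggplot2::aes(x = .data$gpo2, y = .data$mean)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0, colour = "grey40") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "GPO2 (mmHg)", y = "MPO2 (mmHg, replicate mean ± SD)",
                  title = sprintf("%s noise, FWHM %.0f%%", object$target,
                                  100 * object$fwhm_fraction)) +
    ggplot2::theme_minimal()
}
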