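#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an MPO2/GPO2 regression
#'
#' @param x An `mvif_regression`.
#' @param ... Unused.
#' @return One row per model term (`intercept`, `slope`) with `estimate`,
#'   `std.error`, `statistic`, `p.value`.
#' @export
tidy.mvif_regression <- function(x, ...) {
  s <- unname(summary(x$model)$coefficients)
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = s[, 1],
    std.error = s[, 2],
    statistic = s[, 3],
    p.value = s[, 4]
  )
}

#' One-row summary of an MPO2/GPO2 regression
#'
#' @param x An `mvif_regression`.
#' @param ... Unused.
#' @return Tibble with `slope`, `intercept`, `r.squared`, `pearson.r`,
#'   `p.value`, `n`.
#' @export
glance.mvif_regression <- function(x, ...) {
  tibble::tibble(
    slope = x$slope, intercept = x$intercept, r.squared = x$r_squared,
    pearson.r = x$pearson_r, p.value = x$p_value, n = x$n_points
  )
}

#' Tidy an error-propagation result
#' @param x An `error_propagation`.
#' @param ... Unused.
#' @return The per-voxel tibble with replicate mean, SD, SE and CV.
#' @export
tidy.error_propagation <- function(x, ...) x$voxels

#' One-row summary of an error-propagation result
#' @param x An `error_propagation`.
#' @param ... Unused.
#' @export
glance.error_propagation <- function(x, ...) {
  tibble::tibble(target = x$target, fwhm_fraction = x$fwhm_fraction,
                 n_replicates = x$n_replicates,
                 average_cv = x$average_cv, seed = x$seed)
}
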