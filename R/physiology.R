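#' Physiological parameter set for oxygen transport
#'
#' Bundles the blood and tissue constants used by both the Green's-function
#' reference solver and the voxel fusion model. Defaults are the tumor
#' parameter set; a brain preset is available via `preset = "brain"`.
#' All quantities are kept in canonical units: micrometres, seconds, mmHg
#' and micromolar (\eqn{\mu}M).
#'
#' @param preset `"tumor"` (default) or `"brain"`. The two presets differ
#'   only in the maximum oxygen consumption rate `M0`.
#' @param H Henry constant for free oxygen in blood/tissue (mmHg/µM).
#' @param D Oxygen diffusion constant in tissue (µm²/s).
#' @param C_prime Oxygen-binding capacity of fully saturated hemoglobin per
#'   blood volume (µM).
#' @param n_hill Hill coefficient of the oxygen-hemoglobin dissociation
#'   curve (dimensionless).
#' @param P50 Half-saturation oxygen pressure of hemoglobin (mmHg).
#' @param M0 Maximum oxygen consumption rate. Either already canonical
#'   (µM/s) or convertible via `M0_unit`.
#' @param M0_unit Unit tag for `M0`; one of `"uM_per_s"` or
#'   `"cm3O2_per_cm3_per_s"` (converted with the STP molar volume,
#'   22,400 cm³/mol).
#' @param Km Michaelis-Menten half-rate pressure (mmHg). Not a measured
#'   constant of the simulated tissues; the default of 1 mmHg is the value
#'   conventionally used with Michaelis-Menten oxygen sinks in
#'   microvascular transport models, and it is deliberately exposed here
#'   because the hypoxic tail of the solution is sensitive to it.
#' @param alpha_blood Oxygen solubility in blood (µM/mmHg). Defaults to
#'   `1/H` so that free oxygen in plasma follows the same Henry relation
#'   as tissue; override only when modelling a distinct blood solubility.
#'
#' @return An object of class `physiology_params`: a named list with the
#'   canonical-unit constants.
#' @examples
#' p <- physiology_params()
#' p$M0  # 0.0004 cm3/cm3/s converted to ~17.86 uM/s
#' physiology_params("brain")$M0
#' @export
physiology_params <- function(preset = c("tumor", "brain"),
                              H = 0.74,
                              D = 2000,
                              C_prime = 8800,
                              n_hill = 3,
                              P50 = 26,
                              M0 = NULL,
                              M0_unit = "cm3O2_per_cm3_per_s",
                              Km = 1,
                              alpha_blood = NULL) {
  preset <- match.arg(preset)
  if (is.null(M0)) {
    M0 <- switch(preset, tumor = 0.0004, brain = 0.0025)
    M0_unit <- "cm3O2_per_cm3_per_s"
  }
  M0 <- to_canonical_units(M0, M0_unit)
  if (is.null(alpha_blood)) alpha_blood <- 1 / H
  p <- list(
    H = H, D = D, C_prime = C_prime, n_hill = n_hill, P50 = P50,
    M0 = M0, Km = Km, alpha_blood = alpha_blood, preset = preset,
    canonical = TRUE
  )
  vals <- unlist(p[c("H", "D", "C_prime", "n_hill", "P50", "M0", "Km", "alpha_blood")])
  if (any(!is.finite(vals)) || any(vals[setdiff(names(vals), "C_prime")] <= 0) ||
      C_prime < 0) {
    stop("physiology_params: all constants must be finite and positive ",
         "(C_prime may be zero).", call. = FALSE)
  }
  if (n_hill < 1) stop("physiology_params: n_hill must be >= 1.", call. = FALSE)
  structure(p, class = "physiology_params")
}

#' @export
print.physiology_params <- function(x, ...) {
  cat("<physiology_params> preset:", x$preset, "\n")
  cat(sprintf("  H = %.3g mmHg/uM, D = %.4g um^2/s, C' = %.4g uM\n",
              x$H, x$D, x$C_prime))
  cat(sprintf("  Hill: n = %.3g, P50 = %.3g mmHg\n", x$n_hill, x$P50))
  cat(sprintf("  M0 = %.4g uM/s, Km = %.3g mmHg, alpha_blood = %.4g uM/mmHg\n",
              x$M0, x$Km, x$alpha_blood))
  invisible(x)
}

#' Convert a physiological quantity to canonical units
#'
#' Canonical units are µm, s, mmHg and µM. Oxygen volume fractions
#' (cm³ O2 per cm³ tissue) are converted to molar concentration with the
#' ideal-gas molar volume at STP, 22,400 cm³/mol.
#'
#' @param x Numeric quantity.
#' @param unit Unit tag. Recognized: `"uM_per_s"`, `"cm3O2_per_cm3_per_s"`,
#'   `"um2_per_s"`, `"mmHg"`, `"uM"`, `"mmHg_per_uM"`, `"uM_per_mmHg"`,
#'   `"ul_per_g_per_mmHg"` (blood O2 solubility; assumes blood density
#'   1 g/cm³).
#' @return Numeric in canonical units.
#' @examples
#' to_canonical_units(0.0004, "cm3O2_per_cm3_per_s") # ~17.86 uM/s
#' @export
to_canonical_units <- function(x, unit) {
  # mol per cm3 O2 at STP
  per_cm3 <- 1 / 22400
  switch(unit,
    uM_per_s = ,
    um2_per_s = ,
    mmHg = ,
    uM = ,
    mmHg_per_uM = ,
    uM_per_mmHg = x,
    # cm3 O2 / cm3 / s -> mol/cm3/s -> mol/L/s (x1000) -> uM/s (x1e6)
    cm3O2_per_cm3_per_s = x * per_cm3 * 1000 * 1e6,
    # ul O2 / g / mmHg ~ 1e-3 cm3 O2 / cm3 blood / mmHg -> uM/mmHg
    ul_per_g_per_mmHg = x * 1e-3 * per_cm3 * 1000 * 1e6,
    stop("to_canonical_units: unknown unit tag '", unit, "'", call. = FALSE)
  )
}

#' Hill oxygen-hemoglobin dissociation curve
#'
#' Fractional hemoglobin saturation at oxygen pressure `P`:
#' \eqn{S(P) = P^n / (P^n + P_{50}^n)}.
#'
#' @param P Oxygen partial pressure (mmHg), non-negative; vectorized.
#' @param params A [physiology_params()] object.
#' @return Saturation fraction in \[0, 1\].
#' @examples
#' p <- physiology_params()
#' hill_saturation(26, p)  # 0.5 at P50
#' @export
hill_saturation <- function(P, params) {
  if (any(P < 0, na.rm = TRUE)) {
    stop("hill_saturation: P must be >= 0.", call. = FALSE)
  }
  Pn <- (P / params$P50)^params$n_hill
  Pn / (Pn + 1)
}

#' Inverse Hill curve: pressure at a given saturation
#'
#' \eqn{P(S) = P_{50} (S / (1 - S))^{1/n}}. `S = 0` maps to 0 mmHg;
#' `S = 1` has no finite pressure and is an error.
#'
#' @param S Saturation fraction in \[0, 1); vectorized.
#' @inheritParams hill_saturation
#' @return Oxygen pressure (mmHg).
#' @export
hill_inverse <- function(S, params) {
  if (any(S < 0 | S >= 1, na.rm = TRUE)) {
    stop("hill_inverse: S must lie in [0, 1); S = 1 is unbounded.",
         call. = FALSE)
  }
  params$P50 * (S / (1 - S))^(1 / params$n_hill)
}

#' Slope factor of the dissociation curve
#'
#' The dimensionless slope factor \eqn{m = H C' \, dS/dP} used by the
#' voxel fusion model to weight hemoglobin-bound versus dissolved oxygen
#' in the advection term.
#'
#' @param P Oxygen pressure (mmHg), strictly positive; vectorized.
#' @inheritParams hill_saturation
#' @return Non-negative slope factor.
#' @export
hill_slope_m <- function(P, params) {
  if (any(P <= 0, na.rm = TRUE)) {
    stop("hill_slope_m: P must be > 0.", call. = FALSE)
  }
  n <- params$n_hill
  P50n <- params$P50^n
  dSdP <- n * P^(n - 1) * P50n / (P^n + P50n)^2
  params$H * params$C_prime * dSdP
}

#' Michaelis-Menten oxygen consumption rate
#'
#' \eqn{M(P) = M_0 P / (P + K_m)}; the oxygen sink law shared by the
#' reference solver and (optionally) the fusion model.
#'
#' @param P Oxygen pressure (mmHg), non-negative; vectorized.
#' @inheritParams hill_saturation
#' @return Consumption rate (µM/s), in \[0, `M0`\].
#' @export
michaelis_menten_rate <- function(P, params) {
  P <- pmax(P, 0)
  params$M0 * P / (P + params$Km)
}

#' Total oxygen content of blood per unit blood volume
#'
#' Dissolved plus hemoglobin-bound oxygen:
#' \eqn{c(P) = \alpha_b P + C' S(P)} (µM).
#'
#' @inheritParams hill_saturation
#' @return Oxygen content (µM).
#' @keywords internal
blood_o2_content <- function(P, params) {
  params$alpha_blood * P + params$C_prime * hill_saturation(P, params)
}

#' Invert blood oxygen content to pressure
#'
#' Newton iteration for P such that `blood_o2_content(P) == content`,
#' with a bisection fallback. Content below zero maps to 0 mmHg.
#'
#' @param content Oxygen content (µM); vectorized.
#' @inheritParams hill_saturation
#' @param P_init Optional starting pressure(s).
#' @keywords internal
blood_o2_pressure <- function(content, params, P_init = NULL) {
  content <- pmax(content, 0)
  P <- if (is.null(P_init)) pmax(content * params$H / 10, 1) else pmax(P_init, 1e-3)
  for (i in seq_len(60)) {
    f <- blood_o2_content(P, params) - content
    df <- params$alpha_blood + hill_slope_m(pmax(P, 1e-9), params) / params$H
    step <- f / df
    P_new <- P - step
    # guard: keep positive, halve overshoots
    bad <- P_new <= 0
    P_new[bad] <- P[bad] / 2
    if (max(abs(P_new - P)) < 1e-10) {
      P <- P_new
      break
    }
    P <- P_new
  }
  P[content == 0] <- 0
  P
}
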