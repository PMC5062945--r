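#' Radial form factor of the voxel vessel model
#'
#' Krogh-Erlang annulus solution for radial diffusion with a sealed outer
#' boundary at `rT`:
#' \deqn{G_1(r) = r_T^2 \ln(r/r_c) - (r^2 - r_c^2)/2 \quad (\mu m^2).}
#' The radial pO2 drop from the vessel wall is
#' \eqn{(M H / 2D) G_1(r)}.
#'
#' @param r Radial position (µm), in `[rc, rT]`; vectorized.
#' @param rc Vessel radius (µm).
#' @param rT Tissue cylinder radius (µm), `> rc`.
#' @return Form factor (µm²), zero at `r = rc`.
#' @export
form_factor_g1 <- function(r, rc, rT) {
  if (any(r < rc - 1e-9 | r > rT + 1e-9)) {
    stop("form_factor_g1: r must lie in [rc, rT].", call. = FALSE)
  }
  rT^2 * log(r / rc) - (r^2 - rc^2) / 2
}

#' Axial form factor of the voxel vessel model
#'
#' Dimensionless advection term from the axial blood oxygen mass balance:
#' \deqn{G_2(z) = (z/L)(1 - r_c^2/r_T^2).}
#' The axial pO2 drop at position z is \eqn{[M H / ((1+m) F)] G_2(z)}.
#'
#' @param z Axial position (µm), in `[0, L]`; vectorized.
#' @param rc Vessel radius (µm).
#' @param rT Tissue cylinder radius (µm).
#' @param L Voxel edge / vessel length (µm).
#' @return Dimensionless form factor, zero at the inlet.
#' @export
form_factor_g2 <- function(z, rc, rT, L) {
  if (any(z < -1e-9 | z > L + 1e-9)) {
    stop("form_factor_g2: z must lie in [0, L].", call. = FALSE)
  }
  (z / L) * (1 - rc^2 / rT^2)
}

# Volume-weighted annulus average of G1 over rc <= r <= rT (closed form).
g1_annulus_mean <- function(rc, rT) {
  t1 <- rT^2 * (rT^2 * log(rT / rc) - (rT^2 - rc^2) / 2)
  t2 <- (rT^4 - rc^4) / 4 - rc^2 * (rT^2 - rc^2) / 2
  (t1 - t2) / (rT^2 - rc^2)
}

#' Effective voxel inputs for the single-vessel fusion model
#'
#' Bundles the per-voxel quantities the fusion model consumes. `rT`
#' defaults to \eqn{L/\sqrt{\pi}} so that the tissue cylinder volume
#' \eqn{\pi r_T^2 L} equals the voxel volume \eqn{L^3}.
#'
#' @param P_in Inlet pO2 (mmHg), the model's `pO2(z = 0)`.
#' @param F_perf Blood perfusion per tissue volume (1/s).
#' @param rc Effective vessel radius (µm).
#' @param L Voxel edge length (µm).
#' @param m Dissociation-curve slope factor (dimensionless), typically
#'   [hill_slope_m()] evaluated at `P_in`.
#' @param params A [physiology_params()].
#' @param rT Tissue cylinder radius (µm); default `L / sqrt(pi)`.
#' @param M Oxygen consumption rate (µM/s); default `params$M0` (the
#'   Michaelis-Menten coupling in [mvif_voxel_average()] adjusts it).
#' @return List of class `mvif_inputs`.
#' @export
mvif_inputs <- function(P_in, F_perf, rc, L, m, params = physiology_params(),
                        rT = L / sqrt(pi), M = params$M0) {
  if (!is.finite(rc) || rc <= 0 || rc >= rT) {
    stop("mvif_inputs: need 0 < rc < rT.", call. = FALSE)
  }
  if (P_in < 0) stop("mvif_inputs: P_in must be >= 0.", call. = FALSE)
  structure(list(P_in = P_in, F_perf = F_perf, rc = rc, rT = rT, L = L,
                 m = m, M = M, params = params),
            class = "mvif_inputs")
}

#' Pointwise pO2 of the voxel vessel model
#'
#' \deqn{pO_2(r, z) = pO_2(0) - \frac{M H}{(1+m) F} G_2(z)
#'   - \frac{M H}{2 D} G_1(r),}
#' clamped at zero (an attribute `clamped` marks whether clamping fired).
#'
#' @param r,z Cylindrical coordinates (µm); vectorized (recycled).
#' @param inputs An [mvif_inputs()].
#' @return pO2 (mmHg) with attribute `clamped`.
#' @export
mvif_pointwise <- function(r, z, inputs) {
  p <- inputs$params
  if (inputs$F_perf <= 0) {
    stop("mvif_pointwise: F = 0 is perfusion-limited degenerate (advection ",
         "term unbounded).", call. = FALSE)
  }
  g1 <- form_factor_g1(r, inputs$rc, inputs$rT)
  g2 <- form_factor_g2(z, inputs$rc, inputs$rT, inputs$L)
  val <- inputs$P_in -
    inputs$M * p$H / ((1 + inputs$m) * inputs$F_perf) * g2 -
    inputs$M * p$H / (2 * p$D) * g1
  out <- pmax(val, 0)
  attr(out, "clamped") <- any(val < 0)
  out
}

#' Voxel-average pO2 of the fusion model (MPO2)
#'
#' Volume-weighted mean of [mvif_pointwise()] over the tissue annulus
#' `rc <= r <= rT`, `0 <= z <= L`. When no clamping occurs the average is
#' the closed form
#' \eqn{P_{in} - [M H/((1+m)F)] \langle G_2 \rangle - [M H/(2D)] \langle G_1 \rangle};
#' when the pointwise field clips at zero, Gauss-Legendre quadrature of
#' the clamped field is used instead. With `couple_mm = TRUE` (default)
#' the consumption rate is iterated through the Michaelis-Menten law,
#' \eqn{M \leftarrow M(MPO2)}, to self-consistency (0.01 mmHg, max 50
#' iterations), mirroring the reference solver's sink law.
#'
#' @param inputs An [mvif_inputs()].
#' @param couple_mm Iterate Michaelis-Menten consumption (default `TRUE`);
#'   `FALSE` holds `M` fixed (pure Krogh mode).
#' @param n_quad Gauss-Legendre nodes per dimension for the clamped case.
#' @return List: `mpo2` (mmHg), `M` (final consumption µM/s), `clamped`
#'   (logical), `iterations`.
#' @export
mvif_voxel_average <- function(inputs, couple_mm = TRUE, n_quad = 48) {
  p <- inputs$params
  if (inputs$F_perf <= 0 || !is.finite(inputs$rc)) {
    return(list(mpo2 = NA_real_, M = NA_real_, clamped = NA, iterations = 0L))
  }
  g1_bar <- g1_annulus_mean(inputs$rc, inputs$rT)
  g2_bar <- (1 - inputs$rc^2 / inputs$rT^2) / 2
  gq <- gauss_legendre(n_quad)
  avg_for_M <- function(M) {
    a2 <- M * p$H / ((1 + inputs$m) * inputs$F_perf)
    a1 <- M * p$H / (2 * p$D)
    # no clamping anywhere iff the minimum (r = rT, z = L) is >= 0
    min_val <- inputs$P_in - a2 * form_factor_g2(inputs$L, inputs$rc,
                                                 inputs$rT, inputs$L) -
      a1 * form_factor_g1(inputs$rT, inputs$rc, inputs$rT)
    if (min_val >= 0) {
      return(list(mpo2 = inputs$P_in - a2 * g2_bar - a1 * g1_bar,
                  clamped = FALSE))
    }
    # clamped field: 2-D quadrature, radial weight r
    r <- inputs$rc + (inputs$rT - inputs$rc) * gq$x
    z <- inputs$L * gq$x
    wr <- gq$w * (inputs$rT - inputs$rc)
    wz <- gq$w * inputs$L
    vals <- outer(
      inputs$P_in - a1 * form_factor_g1(r, inputs$rc, inputs$rT),
      a2 * form_factor_g2(z, inputs$rc, inputs$rT, inputs$L),
      "-"
    )
    vals <- pmax(vals, 0)
    num <- as.numeric((wr * r) %*% vals %*% wz)
    den <- sum(wr * r) * sum(wz)
    list(mpo2 = num / den, clamped = TRUE)
  }
  M <- inputs$M
  iterations <- 0L
  res <- avg_for_M(M)
  if (couple_mm) {
    for (i in seq_len(50)) {
      iterations <- i
      M_new <- michaelis_menten_rate(res$mpo2, p)
      res_new <- avg_for_M(M_new)
      if (abs(res_new$mpo2 - res$mpo2) < 0.01) {
        res <- res_new
        M <- M_new
        break
      }
      res <- res_new
      M <- M_new
    }
  }
  list(mpo2 = res$mpo2, M = M, clamped = res$clamped,
       iterations = iterations)
}

# Gauss-Legendre nodes/weights on [0, 1] (Golub-Welsch).
gauss_legendre <- function(n) {
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  x <- (rev(e$values) + 1) / 2
  w <- 2 * (e$vectors[1, ]^2)
  list(x = x, w = rev(w) / 2)
}
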