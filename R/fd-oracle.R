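#' Finite-difference solve of the steady reaction-diffusion equation
#'
#' Second-order node-centred finite-difference solution of
#' \eqn{D \alpha \nabla^2 P = k(x) P - s(x)} with zero-flux (sealed)
#' boundaries, by red-black successive over-relaxation. The linearized
#' sink coefficient `k` (µM/s/mmHg per node) is typically the lagged
#' Michaelis-Menten coefficient \eqn{M_0 / (P + K_m)}.
#'
#' @param lattice A [tissue_lattice()] defining the grid.
#' @param source Array (lattice dims) of oxygen input rates (µM µm³/s per
#'   node).
#' @param k Array of linear sink coefficients; scalar 0 allowed only when
#'   the net source is zero (otherwise the sealed problem has no steady
#'   solution and an error is raised).
#' @param params A [physiology_params()] (supplies `D` and `H`).
#' @param tol Relative residual target (vs the source norm). Default 1e-8.
#' @param max_sweeps Maximum SOR sweeps.
#' @param P0 Optional starting field.
#' @return The pO2 array (mmHg).
#' @export
fd_diffusion_solve <- function(lattice, source, k, params,
                               tol = 1e-8, max_sweeps = 20000, P0 = NULL) {
  d <- lattice$dims
  h <- lattice$h
  D_alpha <- params$D / params$H
  A <- D_alpha / h^2
  if (length(k) == 1) k <- array(k, d)
  s <- source / h^3  # uM/s per node volume
  if (all(k == 0)) {
    if (abs(sum(source)) > 1e-9 * max(abs(source), 1e-300)) {
      stop("fd_diffusion_solve: sealed box with net source and no sink ",
           "has no steady solution.", call. = FALSE)
    }
  }
  P <- if (is.null(P0)) array(0, d) else P0
  g <- expand.grid(i = seq_len(d[1]), j = seq_len(d[2]), k = seq_len(d[3]))
  red <- array((g$i + g$j + g$k) %% 2 == 0, d)
  omega <- 2 / (1 + sin(pi / max(d)))
  s_norm <- sqrt(mean(s^2)) + 1e-300
  nb_sum <- function(P) {
    # replicate padding = finite-volume zero-flux boundaries
    out <- array(0, d)
    out <- out + P[c(1, seq_len(d[1] - 1)), , , drop = FALSE]
    out <- out + P[c(seq_len(d[1] - 1) + 1, d[1]), , , drop = FALSE]
    out <- out + P[, c(1, seq_len(d[2] - 1)), , drop = FALSE]
    out <- out + P[, c(seq_len(d[2] - 1) + 1, d[2]), , drop = FALSE]
    out <- out + P[, , c(1, seq_len(d[3] - 1)), drop = FALSE]
    out <- out + P[, , c(seq_len(d[3] - 1) + 1, d[3]), drop = FALSE]
    out
  }
  denom <- 6 * A + k
  k_tot <- sum(k)
  for (sweep in seq_len(max_sweeps)) {
    for (phase in list(red, !red)) {
      nb <- nb_sum(P)
      P_gs <- (A * nb + s) / denom
      P[phase] <- (1 - omega) * P[phase] + omega * P_gs[phase]
    }
    # deflate the slow near-constant Neumann mode: shift P so the global
    # source/sink balance holds exactly (the sealed steady state requires
    # sum(s) = sum(k P))
    if (k_tot > 0) P <- P + (sum(s) - sum(k * P)) / k_tot
    if (sweep %% 10 == 0 || sweep == max_sweeps) {
      resid <- A * (nb_sum(P) - 6 * P) - k * P + s
      if (sqrt(mean(resid^2)) < tol * s_norm) return(P)
    }
  }
  resid <- A * (nb_sum(P) - 6 * P) - k * P + s
  if (sqrt(mean(resid^2)) >= tol * s_norm * 100) {
    stop("fd_diffusion_solve: SOR did not converge in ", max_sweeps,
         " sweeps.", call. = FALSE)
  }
  P
}

#' Brute-force finite-difference reference oxygen field
#'
#' Independent oracle for [solve_reference_field()]: solves the same
#' coupled problem (vessel release matched to wall pO2, blood oxygen
#' marching with the Hill curve, Michaelis-Menten tissue sink) but with a
#' second-order finite-difference discretization on a sealed grid instead
#' of Green's-function superposition. Vessel subsegments are deposited as
#' line sources onto the grid; wall pO2 is sampled on a ring two grid
#' spacings from the axis and corrected down to the vessel radius with the
#' local Krogh annulus solution.
#'
#' @param net A [vessel_network()] with solved flows.
#' @param params A [physiology_params()].
#' @param h Grid spacing (µm); use h/2 of the superposition lattice for a
#'   sharper oracle on small fixtures (<= ~1e6 cells).
#' @param margin Tissue margin (µm) around the domain box.
#' @param ds Subsegment length (µm).
#' @param tol Inner SOR relative residual.
#' @param q_tol Wall-matching tolerance (mmHg).
#' @param max_outer Maximum outer (release/consumption) iterations.
#' @param damping Damping on the release update.
#' @return List of class `reference_field` (same shape as
#'   [solve_reference_field()]).
#' @export
fd_oracle <- function(net, params = physiology_params(), h = 15,
                      margin = 75, ds = 50, tol = 1e-8, q_tol = 0.05,
                      max_outer = 80, damping = 0.5) {
  dd <- discretize(net, h = h, ds = ds, margin = margin)
  lattice <- dd$lattice
  if (prod(lattice$dims) > 2e6) {
    stop("fd_oracle: grid too large (", prod(lattice$dims),
         " cells); the oracle is for small fixtures.", call. = FALSE)
  }
  src <- dd$sources
  n_src <- nrow(src)
  onet <- orient_by_flow(net)
  march <- build_march_plan(onet, src, params)
  D_alpha <- params$D / params$H

  # trilinear deposit stencils for each subsegment (pieces <= h/2 long)
  deposit <- vector("list", n_src)
  d <- lattice$dims
  for (j in seq_len(n_src)) {
    p0 <- c(src$x0[j], src$y0[j], src$z0[j])
    p1 <- c(src$x1[j], src$y1[j], src$z1[j])
    npc <- max(2L, ceiling(src$ds[j] / (h / 2)))
    tt <- (seq_len(npc) - 0.5) / npc
    pts <- cbind(p0[1] + tt * (p1[1] - p0[1]),
                 p0[2] + tt * (p1[2] - p0[2]),
                 p0[3] + tt * (p1[3] - p0[3]))
    fx <- (pts[, 1] - lattice$origin[1]) / h
    fy <- (pts[, 2] - lattice$origin[2]) / h
    fz <- (pts[, 3] - lattice$origin[3]) / h
    i0 <- pmin(pmax(floor(fx), 0), d[1] - 2)
    j0 <- pmin(pmax(floor(fy), 0), d[2] - 2)
    k0 <- pmin(pmax(floor(fz), 0), d[3] - 2)
    tx <- fx - i0; ty <- fy - j0; tz <- fz - k0
    idx <- integer(0); wts <- numeric(0)
    for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
      w <- (if (di) tx else 1 - tx) * (if (dj) ty else 1 - ty) *
        (if (dk) tz else 1 - tz) / npc
      lin <- (i0 + di) + d[1] * ((j0 + dj) + d[2] * (k0 + dk)) + 1
      idx <- c(idx, lin); wts <- c(wts, w)
    }
    keep <- wts > 0
    agg <- rowsum(wts[keep], idx[keep])
    deposit[[j]] <- list(idx = as.integer(rownames(agg)), w = as.numeric(agg))
  }
  # ring sampling points (radius 2h) and self coefficients
  ring <- vector("list", n_src)
  for (j in seq_len(n_src)) {
    ax <- c(src$x1[j] - src$x0[j], src$y1[j] - src$y0[j], src$z1[j] - src$z0[j])
    ax <- ax / sqrt(sum(ax^2))
    e1 <- if (abs(ax[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    e1 <- e1 - sum(e1 * ax) * ax
    e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(ax[2] * e1[3] - ax[3] * e1[2],
            ax[3] * e1[1] - ax[1] * e1[3],
            ax[1] * e1[2] - ax[2] * e1[1])
    ang <- seq(0, 2 * pi, length.out = 9)[-9]
    rs <- 2 * h
    ring[[j]] <- sweep(outer(cos(ang), e1) * rs + outer(sin(ang), e2) * rs,
                       2, c(src$x[j], src$y[j], src$z[j]), "+")
  }
  g_self <- vapply(seq_len(n_src), function(j) {
    ell <- src$ds[j]; rc <- src$radius_um[j]
    2 * log((ell / 2 + sqrt(ell^2 / 4 + rc^2)) / rc) / (4 * pi * D_alpha * ell)
  }, numeric(1))

  q <- rep(0, n_src)
  P <- array(0, d)
  rs <- 2 * h
  mismatch_hist <- numeric(0)
  for (outer in seq_len(max_outer)) {
    s_arr <- array(0, d)
    for (j in seq_len(n_src)) {
      s_arr[deposit[[j]]$idx] <- s_arr[deposit[[j]]$idx] + q[j] * deposit[[j]]$w
    }
    k_arr <- params$M0 / (pmax(P, 0) + params$Km)
    P <- fd_diffusion_solve(lattice, s_arr, k_arr, params,
                            tol = tol, P0 = P)
    P_ring <- vapply(seq_len(n_src), function(j) {
      mean(trilinear_at(lattice, P, ring[[j]]))
    }, numeric(1))
    # analytic continuation of the ring value down to the wall radius
    M_loc <- michaelis_menten_rate(P_ring, params)
    rc <- src$radius_um
    lam <- q / src$ds
    A_coef <- -lam / (2 * pi * D_alpha) - (M_loc / (2 * D_alpha)) * rc^2
    P_wall <- P_ring - (M_loc / (4 * D_alpha)) * (rs^2 - rc^2) -
      A_coef * log(rs / rc)
    blood <- march_blood(march, q, params)
    mism <- blood$P_mid - P_wall
    # wall response to release: local self-potential plus the global sealed
    # response (a release increment raises the whole box by 1/sum(k))
    g_eff <- g_self + 1 / (h^3 * sum(k_arr))
    q <- q + damping * mism / g_eff
    q <- pmax(q, 0)
    mismatch_hist <- c(mismatch_hist, max(abs(mism)))
    if (max(abs(mism)) < q_tol) break
  }
  blood <- march_blood(march, q, params)
  lattice$lpo2 <- P
  src$q <- q
  src$blood_po2 <- blood$P_mid
  src$sao2 <- hill_saturation(pmax(blood$P_mid, 0), params)
  structure(list(
    lattice = lattice, sources = src, net = net, params = params,
    diagnostics = list(
      iterations = length(mismatch_hist),
      residuals = mismatch_hist,
      total_release = sum(q),
      total_consumption = sum(michaelis_menten_rate(P, params) * h^3),
      balance_error = abs(sum(q) -
        sum(michaelis_menten_rate(P, params) * h^3)) / max(sum(q), 1e-12)
    )
  ), class = "reference_field")
}
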