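#' Steady-state reference oxygen field by Green's-function superposition
#'
#' Computes the tissue lattice pO2 (LPO2) generated by all vessel
#' subsegment sources under Michaelis-Menten consumption. The tissue field
#' is the superposition
#' \deqn{P(x) = \sum_j q_j G(x - x_j) - \sum_k M(P_k) V_k G(x - y_k)}
#' with the free-space diffusion kernel \eqn{G(r) = 1/(4\pi D \alpha r)}
#' regularized at the lattice scale. Subsegment release rates `q` are set
#' so that the vessel-wall tissue pO2 matches the intravascular blood pO2,
#' which itself declines along each flow path as oxygen (dissolved plus
#' hemoglobin-bound, via the Hill curve) is released. The coupled
#' nonlinear system in (tissue field, release rates) is solved by a
#' globalized Newton iteration with matrix-free BiCGSTAB linear solves.
#'
#' Vessel sources are treated as finite line sources (exact uniform-line
#' kernel) rather than bare points; this sharpens the near field without
#' changing the far field. Tissue sinks sit at lattice points with weight
#' \eqn{h^3} and are convolved with the kernel by FFT, which is an exact
#' (accelerated) evaluation of the double sum above.
#'
#' @param net A [vessel_network()] with solved flows and inlet saturations.
#' @param lattice,sources Output of [discretize()]; built automatically
#'   when `NULL`.
#' @param params A [physiology_params()].
#' @param tol Convergence tolerance: maximum residual (mmHg) of the
#'   tissue and wall-matching equations. Default 0.01 mmHg.
#' @param max_iter Maximum Newton iterations.
#' @param h,ds,margin Passed to [discretize()] when `lattice` is `NULL`.
#' @param verbose Print per-iteration residuals.
#' @return List of class `reference_field`:
#'   `lattice` (with `lpo2` filled), `sources` (tibble with release `q`,
#'   midpoint blood pO2 `blood_po2`, `sao2`), `net` (segments annotated
#'   with `blood_po2_in` / `blood_po2_out`), `params`, and `diagnostics`
#'   (iterations, residual history, total release and consumption).
#' @export
solve_reference_field <- function(net, lattice = NULL, sources = NULL,
                                  params = physiology_params(),
                                  tol = 0.01, max_iter = 60,
                                  h = 15, ds = 50, margin = 75,
                                  verbose = FALSE) {
  if (any(!is.finite(net$segments$flow_um3_s))) {
    stop("solve_reference_field: segment flows are unset; run ",
         "solve_hemodynamics() first.", call. = FALSE)
  }
  if (is.null(lattice) || is.null(sources)) {
    dd <- discretize(net, h = h, ds = ds, margin = margin)
    lattice <- dd$lattice
    sources <- dd$sources
  }
  onet <- orient_by_flow(net)
  march <- build_march_plan(onet, sources, params)
  src <- march$sources
  n_src <- nrow(src)
  D_alpha <- params$D / params$H
  hh <- lattice$h

  pts_lat <- lattice_points_matrix(lattice)
  # vessel -> tissue potentials (line kernel, lattice-scale regularization)
  Avt <- matrix(0, nrow(pts_lat), n_src)
  for (j in seq_len(n_src)) {
    Avt[, j] <- line_source_potential(
      pts_lat, c(src$x0[j], src$y0[j], src$z0[j]),
      c(src$x1[j], src$y1[j], src$z1[j]), D_alpha,
      rho_min = max(src$radius_um[j], hh / 2))
  }
  # vessel -> vessel-wall potentials; cross terms are regularized at the
  # lattice half-spacing so that collocation points crowded around branch
  # nodes do not produce near-singular (inconsistent) matching rows
  mids <- cbind(src$x, src$y, src$z)
  Avv <- matrix(0, n_src, n_src)
  for (j in seq_len(n_src)) {
    Avv[, j] <- line_source_potential(
      mids, c(src$x0[j], src$y0[j], src$z0[j]),
      c(src$x1[j], src$y1[j], src$z1[j]), D_alpha,
      rho_min = max(src$radius_um[j], hh / 2))
  }
  # self term: potential at own wall (perpendicular distance = radius)
  diag(Avv) <- vapply(seq_len(n_src), function(j) {
    ell <- src$ds[j]
    rc <- src$radius_um[j]
    2 * log((ell / 2 + sqrt(ell^2 / 4 + rc^2)) / rc) / (4 * pi * D_alpha * ell)
  }, numeric(1))
  # flow per subsegment (for the blood-side Jacobian of the wall matching)
  seg_flow <- abs(net$segments$flow_um3_s[match(src$segment,
                                                net$segments$id)])

  convolve_raw <- make_sink_convolver(lattice, D_alpha)
  n_conv <- 0L
  convolve_sinks <- function(x) {
    n_conv <<- n_conv + 1L
    convolve_raw(x)
  }
  Vk <- hh^3

  # Inner problem: given the vessel field A q, solve the integral equation
  # P + G[M(P) V] = A q for the raw tissue field (consumption uses the
  # clamped field). Newton with a frozen Jacobian J = I + G diag(M'(P) V),
  # inner solves by BiCGSTAB with FFT kernel products.
  solve_tissue <- function(vfield, P) {
    for (newton in seq_len(30)) {
      Pc <- pmax(P, 0)
      Fres <- P + convolve_sinks(michaelis_menten_rate(Pc, params) * Vk) -
        vfield
      fn0 <- max(abs(Fres))
      if (fn0 < tol / 4) break
      dM <- ifelse(P > 0,
                   params$M0 * params$Km / (Pc + params$Km)^2 * Vk, 0)
      matvec <- function(x) x + convolve_sinks(dM * x)
      delta <- bicgstab(matvec, -Fres, tol = 3e-2, maxit = 80)
      # line search: halve until the residual norm decreases
      step <- 1
      for (ls in seq_len(8)) {
        P_try <- P + step * delta
        Fn <- max(abs(P_try +
          convolve_sinks(michaelis_menten_rate(pmax(P_try, 0), params) * Vk) -
          vfield))
        if (Fn < fn0) break
        step <- step / 2
      }
      P <- P + step * delta
    }
    P
  }

  # initialize release at a per-subsegment Krogh-cell demand, capped by the
  # oxygen each segment's blood can deliver
  inl <- onet$nodes$role == "inlet"
  c0 <- if (any(inl)) {
    s0 <- mean(onet$nodes$inlet_sao2[inl], na.rm = TRUE)
    params$alpha_blood * hill_inverse(s0, params) + params$C_prime * s0
  } else params$C_prime
  n_sub_seg <- table(src$segment)[as.character(src$segment)]
  cap_blood <- 0.5 * seg_flow * c0 / as.numeric(n_sub_seg)
  demand <- params$M0 * pi * 50^2 * src$ds
  q <- pmin(demand, cap_blood)
  P <- solve_tissue(array(Avt %*% q, lattice$dims), array(0, lattice$dims))

  # Coupled Newton on (P, q): tissue integral equation plus wall matching,
  # with the blood response linearized on its diagonal. Solved matrix-free
  # by BiCGSTAB; q is rescaled by the wall self-potential so that both
  # blocks are O(1).
  n_lat <- prod(lattice$dims)
  Avv_diag <- diag(Avv)
  # consumption with a C1 zero crossing (0.1 mmHg blend, well below Km): keeps
  # the tissue equation differentiable at the hypoxic boundary while anoxic
  # points consume exactly zero
  smooth_cons <- function(P) {
    Ps <- c1_ramp(P, 0.1)
    michaelis_menten_rate(Ps, params) * Vk
  }
  smooth_cons_deriv <- function(P) {
    Ps <- c1_ramp(P, 0.1)
    params$M0 * params$Km / (Ps + params$Km)^2 * Vk *
      c1_ramp_deriv(P, 0.1)
  }
  residual_parts <- function(P, q) {
    sink_field <- convolve_sinks(smooth_cons(P))
    blood <- march_blood(march, q, params)
    F1 <- P + sink_field - array(Avt %*% q, lattice$dims)
    F2 <- as.numeric(Avv %*% q) -
      trilinear_at(lattice, sink_field, mids) - blood$P_mid
    list(F1 = F1, F2 = F2, fnorm = max(max(abs(F1)), max(abs(F2))),
         f1max = max(abs(F1)), f2max = max(abs(F2)))
  }
  res <- residual_parts(P, q)
  residuals <- res$fnorm
  iters <- 0L
  best <- list(P = P, q = q, fnorm = res$fnorm)
  for (it in seq_len(max_iter)) {
    iters <- it
    if (res$fnorm < tol) break
    # plateau: no meaningful progress over the last four steps
    if (it > 8 && utils::tail(residuals, 1) >
          0.98 * max(utils::tail(residuals, 4))) break
    Dk <- smooth_cons_deriv(P)
    blood <- march_blood(march, q, params)
    cp <- params$alpha_blood +
      hill_slope_m(pmax(blood$P_mid, 1e-3), params) / params$H
    # blood-path sensitivity: releasing dq at or upstream of a subsegment
    # lowers its blood pO2 by ~ ramp'/(Q c'(P)) dq, propagated through the
    # flow DAG by the exact linearized march
    wj <- c1_ramp_deriv(blood$c_raw_mid, 40) /
      (pmax(seg_flow, 1e-9) * cp)
    # per-column equilibration: each wall equation's diagonal ~ 1 even when
    # the blood response dominates (tiny-flow branches)
    qs <- 1 / (Avv_diag + wj / 2)
    mv <- function(x) {
      xP <- array(x[seq_len(n_lat)], lattice$dims)
      xq <- x[n_lat + seq_len(n_src)] * qs
      gx <- convolve_sinks(Dk * xP)
      yP <- xP + gx - array(Avt %*% xq, lattice$dims)
      yq <- as.numeric(Avv %*% xq) -
        march_blood_jvp(march, blood, cp, xq, params) -
        trilinear_at(lattice, gx, mids)
      c(as.numeric(yP), yq)
    }
    delta <- bicgstab(mv, c(as.numeric(-res$F1), -res$F2),
                      tol = 1e-2, maxit = 70)
    dP_full <- array(delta[seq_len(n_lat)], lattice$dims)
    dq_full <- delta[n_lat + seq_len(n_src)] * qs
    step <- 1
    accepted <- FALSE
    for (ls in seq_len(8)) {
      res_try <- residual_parts(P + step * dP_full, q + step * dq_full)
      if (res_try$fnorm < res$fnorm * (1 + 1e-3)) {
        accepted <- TRUE
        break
      }
      step <- step / 2
    }
    if (!accepted && res_try$fnorm > res$fnorm * 1.5) {
      # bad direction (linear solve failed); keep state, record and move on
      residuals <- c(residuals, res$fnorm)
      next
    }
    P <- P + step * dP_full
    q <- q + step * dq_full
    res <- res_try
    if (res$fnorm < best$fnorm) best <- list(P = P, q = q, fnorm = res$fnorm)
    residuals <- c(residuals, res$fnorm)
    if (verbose) {
      message(sprintf(
        "  it %3d: resid %.4g (F1 %.3g F2 %.3g)  step %.3g  lin %.3g  sum(q) %.5g  conv %d",
        it, res$fnorm, res$f1max, res$f2max, step,
        attr(delta, "relres"), sum(q), n_conv))
      n_conv <- 0L
    }
  }
  if (best$fnorm < res$fnorm) {
    P <- best$P
    q <- best$q
    res <- residual_parts(P, q)
  }
  if (res$fnorm >= tol * 10) {
    stop("solve_reference_field: no convergence after ", max_iter,
         " iterations; residual history tail: ",
         paste(signif(utils::tail(residuals, 5), 3), collapse = ", "),
         call. = FALSE)
  }
  blood <- march_blood(march, q, params)
  # consumption of the converged solution (the solver's regularized sink
  # law); its gap to total release measures oxygen escaping the lattice
  c_arr <- smooth_cons(P)
  P <- pmax(P, 0)
  lattice$lpo2 <- P
  src$q <- q
  src$blood_po2 <- blood$P_mid
  src$sao2 <- hill_saturation(pmax(blood$P_mid, 0), params)
  seg_tab <- blood$segments
  net$segments <- dplyr::left_join(net$segments, seg_tab, by = c(id = "segment"))
  structure(list(
    lattice = lattice, sources = src, net = net, params = params,
    diagnostics = list(
      iterations = iters, residuals = residuals,
      total_release = sum(q), total_consumption = sum(c_arr),
      balance_error = abs(sum(q) - sum(c_arr)) / max(sum(q), 1e-12)
    )
  ), class = "reference_field")
}

#' @export
print.reference_field <- function(x, ...) {
  d <- x$diagnostics
  cat("<reference_field>\n")
  print(x$lattice)
  cat(sprintf("  %d sources, %d iterations, release %.4g, consumption %.4g (balance %.2f%%)\n",
              nrow(x$sources), d$iterations, d$total_release,
              d$total_consumption, 100 * d$balance_error))
  invisible(x)
}

# Reorient segments so flow is positive from -> to; returns network with a
# "flipped" attribute marking reversed rows.
orient_by_flow <- function(net) {
  segs <- net$segments
  neg <- which(segs$flow_um3_s < 0)
  if (length(neg)) {
    tmp <- segs$from[neg]
    segs$from[neg] <- segs$to[neg]
    segs$to[neg] <- tmp
    segs$flow_um3_s[neg] <- -segs$flow_um3_s[neg]
  }
  net$segments <- segs
  attr(net, "flipped_segments") <- segs$id[neg]
  net
}

# Build the topological marching plan over the flow DAG.
# Returns ordered segment list with per-segment subsegment indices.
build_march_plan <- function(onet, sources, params) {
  segs <- onet$segments
  nodes <- onet$nodes
  # drop zero-flow segments from the march (no convective transport)
  active <- which(segs$flow_um3_s > 1e-12)
  n <- nrow(nodes)
  idx <- stats::setNames(seq_len(n), nodes$id)
  indeg <- integer(n)
  for (s in active) indeg[idx[as.character(segs$to[s])]] <-
    indeg[idx[as.character(segs$to[s])]] + 1L
  # Kahn topological order
  queue <- which(indeg == 0L)
  order_nodes <- integer(0)
  indeg2 <- indeg
  out_of <- split(active, idx[as.character(segs$from[active])])
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    order_nodes <- c(order_nodes, v)
    for (s in out_of[[as.character(v)]]) {
      w <- idx[as.character(segs$to[s])]
      indeg2[w] <- indeg2[w] - 1L
      if (indeg2[w] == 0L) queue <- c(queue, w)
    }
  }
  if (length(order_nodes) < length(unique(c(idx[as.character(segs$from[active])],
                                            idx[as.character(segs$to[active])])))) {
    stop("build_march_plan: flow graph contains a cycle; cannot march ",
         "blood oxygen.", call. = FALSE)
  }
  # order segments by the position of their upstream node
  pos <- match(idx[as.character(segs$from[active])], order_nodes)
  seg_order <- active[order(pos)]
  # match subsegments to oriented segments; subsegments were laid out in the
  # original from->to sense, so reversed segments march their subsegments in
  # reverse index order
  src <- sources
  sub_of <- split(seq_len(nrow(src)), src$segment)
  flipped <- attr(onet, "flipped_segments")
  for (sid in as.character(flipped)) {
    if (!is.null(sub_of[[sid]])) sub_of[[sid]] <- rev(sub_of[[sid]])
  }
  list(sources = src, segs = segs, nodes = nodes, idx = idx,
       seg_order = seg_order, sub_of = sub_of, params = params)
}

# March blood oxygen content along the flow DAG for given release rates q.
# Returns midpoint blood pO2 per subsegment and per-segment in/out pO2.
march_blood <- function(plan, q, params) {
  segs <- plan$segs
  nodes <- plan$nodes
  idx <- plan$idx
  n <- nrow(nodes)
  flux_in <- numeric(n)   # content flux arriving (uM um^3/s)
  q_in <- numeric(n)      # blood flow arriving (um^3/s)
  # inlet boundary content
  P_mid <- rep(NA_real_, nrow(plan$sources))
  c_raw_mid <- rep(-Inf, nrow(plan$sources))
  c_raw_out <- rep(-Inf, nrow(segs))
  seg_in <- rep(NA_real_, nrow(segs))
  seg_out <- rep(NA_real_, nrow(segs))
  inl <- which(nodes$role == "inlet")
  c_node <- rep(NA_real_, n)
  for (v in inl) {
    P0 <- hill_inverse(nodes$inlet_sao2[v], params)
    c_node[v] <- params$alpha_blood * P0 + params$C_prime * nodes$inlet_sao2[v]
  }
  last_P <- NULL
  for (s in plan$seg_order) {
    v <- idx[as.character(segs$from[s])]
    if (is.na(c_node[v])) {
      c_node[v] <- if (q_in[v] > 0) flux_in[v] / q_in[v] else 0
    }
    Q <- segs$flow_um3_s[s]
    subs <- plan$sub_of[[as.character(segs$id[s])]]
    qs <- q[subs]
    cum <- cumsum(qs) - qs / 2
    # C1 floor at zero content (40 uM blend, < 1 % of arterial content):
    # keeps depleted low-flow branches differentiable for the Newton
    # solver; fully depleted blood carries exactly zero
    c_raw <- c_node[v] - cum / Q
    c_raw_mid[subs] <- c_raw
    c_mid <- c1_ramp(c_raw, 40)
    P_mid[subs] <- blood_o2_pressure(c_mid, params)
    c_raw_out[s] <- c_node[v] - sum(qs) / Q
    c_out <- c1_ramp(c_raw_out[s], 40)
    seg_in[s] <- blood_o2_pressure(c_node[v], params)
    seg_out[s] <- blood_o2_pressure(c_out, params)
    w <- idx[as.character(segs$to[s])]
    flux_in[w] <- flux_in[w] + c_out * Q
    q_in[w] <- q_in[w] + Q
  }
  # subsegments of zero-flow segments: no convective supply
  P_mid[is.na(P_mid)] <- 0
  list(P_mid = P_mid, c_raw_mid = c_raw_mid, c_raw_out = c_raw_out,
       segments = tibble::tibble(segment = segs$id,
                                 blood_po2_in = seg_in,
                                 blood_po2_out = seg_out))
}

# Jacobian-vector product of march_blood's midpoint blood pO2 with respect
# to the release rates: the exact linearized march through the flow DAG
# (content perturbations mix at nodes by flow fraction and propagate
# downstream). `blood` is the state returned by march_blood at the current
# q; `cp` is dContent/dP at the midpoints.
march_blood_jvp <- function(plan, blood, cp, xq, params) {
  segs <- plan$segs
  nodes <- plan$nodes
  idx <- plan$idx
  n <- nrow(nodes)
  dflux <- numeric(n)
  qin <- numeric(n)
  dc_node <- rep(0, n)
  is_inlet <- nodes$role == "inlet"
  dPb <- numeric(nrow(plan$sources))
  for (s in plan$seg_order) {
    v <- idx[as.character(segs$from[s])]
    if (!is_inlet[v] && qin[v] > 0) dc_node[v] <- dflux[v] / qin[v]
    Q <- segs$flow_um3_s[s]
    subs <- plan$sub_of[[as.character(segs$id[s])]]
    xs <- xq[subs]
    dcum <- (cumsum(xs) - xs / 2) / Q
    dcraw <- dc_node[v] - dcum
    dPb[subs] <- c1_ramp_deriv(blood$c_raw_mid[subs], 40) * dcraw / cp[subs]
    dcout <- (dc_node[v] - sum(xs) / Q) *
      c1_ramp_deriv(blood$c_raw_out[s], 40)
    w <- idx[as.character(segs$to[s])]
    dflux[w] <- dflux[w] + dcout * Q
    qin[w] <- qin[w] + Q
  }
  dPb
}

# C1 ramp: exactly 0 below -delta, exactly x above +delta, quadratic blend
# between. Unlike a softplus it adds no residual floor on the flat branch,
# so fully depleted / anoxic states carry exactly zero consumption.
c1_ramp <- function(x, delta) {
  ifelse(x <= -delta, 0,
         ifelse(x >= delta, x, (x + delta)^2 / (4 * delta)))
}
c1_ramp_deriv <- function(x, delta) {
  ifelse(x <= -delta, 0,
         ifelse(x >= delta, 1, (x + delta) / (2 * delta)))
}

# Unpreconditioned BiCGSTAB for x in matvec(x) = b (arrays allowed).
# Attribute "relres" records the achieved relative residual.
bicgstab <- function(matvec, b, tol = 1e-6, maxit = 200) {
  x <- b * 0
  r <- b
  r0 <- r
  rho <- alpha <- omega <- 1
  v <- p <- b * 0
  bnorm <- sqrt(sum(b^2)) + 1e-300
  x_best <- x
  r_best <- bnorm
  done <- function(x, rn) {
    attr(x, "relres") <- rn / bnorm
    x
  }
  for (i in seq_len(maxit)) {
    rho1 <- sum(r0 * r)
    if (abs(rho1) < 1e-300) break
    beta <- (rho1 / rho) * (alpha / omega)
    p <- r + beta * (p - omega * v)
    v <- matvec(p)
    alpha <- rho1 / sum(r0 * v)
    s <- r - alpha * v
    if (sqrt(sum(s^2)) < tol * bnorm) {
      return(done(x + alpha * p, sqrt(sum(s^2))))
    }
    t <- matvec(s)
    omega <- sum(t * s) / sum(t * t)
    x <- x + alpha * p + omega * s
    r <- s - omega * t
    rho <- rho1
    rn <- sqrt(sum(r^2))
    if (rn < r_best) {
      r_best <- rn
      x_best <- x
    }
    if (rn < tol * bnorm) return(done(x, rn))
  }
  done(x_best, r_best)
}
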