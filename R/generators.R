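#' Single straight vessel centred in a box
#'
#' The canonical Krogh-type fixture: one axial vessel along z (by default)
#' through the centre of `domain_box`.
#'
#' @param length Vessel length (µm).
#' @param radius Vessel radius (µm).
#' @param flow Volumetric blood flow (µm³/s), directed inlet -> outlet.
#' @param inlet_sao2 Hemoglobin saturation at the inlet, in (0, 1\].
#' @param domain_box `2 x 3` matrix (lo; hi) in µm.
#' @param axis Axis the vessel runs along: 1, 2 or 3 (default z).
#' @return A [vessel_network()] with two nodes and one segment.
#' @export
generate_single_vessel <- function(length = 150, radius = 5, flow = 1e5,
                                   inlet_sao2 = 0.9,
                                   domain_box = rbind(c(0, 0, 0),
                                                      c(150, 150, 150)),
                                   axis = 3) {
  domain_box <- as.matrix(domain_box)
  ext <- domain_box[2, ] - domain_box[1, ]
  if (length > ext[axis]) {
    stop("generate_single_vessel: vessel does not fit in the box.",
         call. = FALSE)
  }
  ctr <- colMeans(domain_box)
  a <- b <- ctr
  a[axis] <- ctr[axis] - length / 2
  b[axis] <- ctr[axis] + length / 2
  nodes <- tibble::tibble(
    id = 1:2,
    x = c(a[1], b[1]), y = c(a[2], b[2]), z = c(a[3], b[3]),
    role = c("inlet", "outlet"),
    pressure = c(NA_real_, NA_real_),
    inlet_sao2 = c(inlet_sao2, NA_real_)
  )
  segs <- tibble::tibble(id = 1L, from = 1L, to = 2L, radius_um = radius,
                         flow_um3_s = flow, hematocrit = 0.45)
  vessel_network(nodes, segs, domain_box)
}

#' Array of parallel vessels
#'
#' `n_vessels` straight vessels along z on a square grid in the x-y plane,
#' optionally jittered; a deterministic fixture that mimics regularly
#' spaced microvessels at imaging resolution.
#'
#' @param n_vessels Number of vessels.
#' @param spacing Centre-to-centre spacing (µm); must exceed twice the
#'   largest radius.
#' @param jitter Uniform positional jitter amplitude (µm) applied in x-y.
#' @param length Vessel length (µm).
#' @param radius_range Range for per-vessel radii (µm), sampled uniformly;
#'   give a single value for identical radii.
#' @param flow_range Range for per-vessel flows (µm³/s).
#' @param inlet_sao2 Inlet saturation: a single value applied to every
#'   vessel, a range sampled uniformly per vessel, or a function of the
#'   vessel centre coordinates `(x, y)` returning one saturation per
#'   vessel (capillaries sharing upstream arterioles have spatially
#'   correlated inputs, so smooth fields are the physiological choice).
#' @param margin Extra tissue margin (µm) added around the vessel bundle in
#'   x and y when building the domain box.
#' @param seed RNG seed; the generator is deterministic for a fixed seed.
#' @return A [vessel_network()].
#' @export
generate_parallel_array <- function(n_vessels = 4, spacing = 75, jitter = 0,
                                    length = 150,
                                    radius_range = c(4, 6),
                                    flow_range = c(5e4, 2e5),
                                    inlet_sao2 = 0.9,
                                    margin = spacing / 2,
                                    seed = 1) {
  if (max(radius_range) * 2 >= spacing) {
    stop("generate_parallel_array: spacing must exceed vessel diameter.",
         call. = FALSE)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  side <- ceiling(sqrt(n_vessels))
  gx <- rep(seq_len(side), each = side)[seq_len(n_vessels)]
  gy <- rep(seq_len(side), times = side)[seq_len(n_vessels)]
  cx <- (gx - 1) * spacing + spacing / 2 + margin - spacing / 2
  cy <- (gy - 1) * spacing + spacing / 2 + margin - spacing / 2
  if (jitter > 0) {
    cx <- cx + stats::runif(n_vessels, -jitter, jitter)
    cy <- cy + stats::runif(n_vessels, -jitter, jitter)
  }
  rads <- if (diff(range(radius_range)) == 0) rep(radius_range[1], n_vessels)
          else stats::runif(n_vessels, radius_range[1], radius_range[2])
  flows <- if (diff(range(flow_range)) == 0) rep(flow_range[1], n_vessels)
           else stats::runif(n_vessels, flow_range[1], flow_range[2])
  sats <- if (is.function(inlet_sao2)) inlet_sao2(cx, cy)
          else if (length(inlet_sao2) == 1) rep(inlet_sao2, n_vessels)
          else stats::runif(n_vessels, inlet_sao2[1], inlet_sao2[2])
  wx <- (max(gx) - 1) * spacing + 2 * margin
  wy <- (max(gy) - 1) * spacing + 2 * margin
  box <- rbind(c(0, 0, 0), c(wx, wy, length))
  nodes <- tibble::tibble(
    id = seq_len(2 * n_vessels),
    x = rep(cx, each = 2), y = rep(cy, each = 2),
    z = rep(c(0, length), times = n_vessels),
    role = rep(c("inlet", "outlet"), times = n_vessels),
    pressure = NA_real_,
    inlet_sao2 = as.vector(rbind(sats, NA_real_))
  )
  segs <- tibble::tibble(
    id = seq_len(n_vessels),
    from = seq(1L, 2L * n_vessels, by = 2L),
    to = seq(2L, 2L * n_vessels, by = 2L),
    radius_um = rads, flow_um3_s = flows, hematocrit = 0.45
  )
  vessel_network(nodes, segs, box)
}

# Save/restore global RNG state so generators do not perturb user streams.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Tumor-like stochastic branching network
#'
#' Grows tortuous branching trees from inlet roots on the domain faces by a
#' biased random walk with stochastic bifurcation, until a target vascular
#' volume fraction is reached. Radii taper from root to tip within
#' `radius_range`; leaves become pressure outlets so that
#' [solve_hemodynamics()] yields a perfused tree. The defaults emulate a
#' window-chamber tumor microvasculature: a thin 990 x 810 x 150 µm slab
#' with heterogeneous radii, tortuous paths and inter-vessel spacing
#' spanning roughly 12-125 µm.
#'
#' @param domain_box `2 x 3` matrix (lo; hi), µm.
#' @param target_vascular_fraction Target vessel volume / domain volume.
#' @param n_roots Number of inlet trees.
#' @param step Mean walk step length (µm).
#' @param branch_prob Per-step bifurcation probability.
#' @param radius_range Radius range (µm): tips get the minimum, roots the
#'   maximum, linearly by depth.
#' @param tortuosity Angular jitter (radians SD) per step.
#' @param inlet_sao2 Inlet saturation.
#' @param max_tries Bounded retries when the target fraction cannot be
#'   placed.
#' @param seed RNG seed (deterministic output for fixed seed).
#' @return A [vessel_network()] (flows unset; call [solve_hemodynamics()]).
#' @export
generate_tumor_like_network <- function(domain_box = rbind(c(0, 0, 0),
                                                           c(990, 810, 150)),
                                        target_vascular_fraction = 0.02,
                                        n_roots = 3,
                                        step = 45,
                                        branch_prob = 0.30,
                                        radius_range = c(3, 15),
                                        tortuosity = 0.45,
                                        inlet_sao2 = 0.9,
                                        max_tries = 8,
                                        seed = 1) {
  domain_box <- as.matrix(domain_box)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  vol_target <- target_vascular_fraction * prod(domain_box[2, ] - domain_box[1, ])
  for (try in seq_len(max_tries)) {
    net <- .grow_tumor_trees(domain_box, vol_target, n_roots, step,
                             branch_prob, radius_range, tortuosity,
                             inlet_sao2)
    if (!is.null(net)) {
      got <- vascular_volume(net)
      if (abs(got - vol_target) / vol_target <= 0.2) return(net)
    }
  }
  stop("generate_tumor_like_network: could not reach the requested ",
       "vascular fraction within ", max_tries, " attempts.", call. = FALSE)
}

.grow_tumor_trees <- function(box, vol_target, n_roots, step, branch_prob,
                              radius_range, tortuosity, inlet_sao2) {
  lo <- box[1, ]; hi <- box[2, ]
  ext <- hi - lo
  max_depth <- 14L
  nodes <- list(); segs <- list()
  nid <- 0L; sid <- 0L
  vol <- 0
  rad_at <- function(depth) {
    f <- pmin(depth / max_depth, 1)
    radius_range[2] - f * (radius_range[2] - radius_range[1])
  }
  # active tips: list of (node id, position, direction, depth)
  tips <- list()
  for (r in seq_len(n_roots)) {
    # roots enter from a random x- or y-face at mid-depth in z
    face <- sample(1:4, 1)
    pos <- lo + stats::runif(3, 0.15, 0.85) * ext
    dir <- switch(face,
                  c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0))
    pos[c(1, 1, 2, 2)[face]] <- if (face %in% c(1, 3)) lo[c(1, 1, 2, 2)[face]] +
      1e-3 else hi[c(1, 1, 2, 2)[face]] - 1e-3
    nid <- nid + 1L
    nodes[[nid]] <- list(id = nid, x = pos[1], y = pos[2], z = pos[3],
                         role = "inlet", pressure = NA_real_,
                         inlet_sao2 = inlet_sao2)
    tips[[length(tips) + 1]] <- list(node = nid, pos = pos, dir = dir,
                                     depth = 0L)
  }
  jitter_dir <- function(d, sdev) {
    d <- d + stats::rnorm(3, 0, sdev)
    # keep walks mostly in-plane for thin slabs
    d[3] <- d[3] * min(1, ext[3] / max(ext))
    d / sqrt(sum(d^2))
  }
  leaf_nodes <- integer(0)
  while (vol < vol_target && length(tips) > 0) {
    new_tips <- list()
    for (tp in tips) {
      if (vol >= vol_target) { leaf_nodes <- c(leaf_nodes, tp$node); next }
      n_child <- if (stats::runif(1) < branch_prob && tp$depth > 0) 2L else 1L
      spawned <- FALSE
      for (ch in seq_len(n_child)) {
        d <- jitter_dir(tp$dir, tortuosity + (n_child == 2) * 0.5)
        len <- step * stats::runif(1, 0.6, 1.4)
        pos2 <- tp$pos + d * len
        # reflect at the domain walls so walks survive in thin slabs
        for (k in 1:3) {
          if (pos2[k] <= lo[k] + 1e-3) {
            pos2[k] <- 2 * (lo[k] + 1e-3) - pos2[k]
            d[k] <- -d[k]
          } else if (pos2[k] >= hi[k] - 1e-3) {
            pos2[k] <- 2 * (hi[k] - 1e-3) - pos2[k]
            d[k] <- -d[k]
          }
        }
        if (any(pos2 <= lo + 1e-3) || any(pos2 >= hi - 1e-3)) next
        depth2 <- tp$depth + 1L
        if (depth2 > max_depth) next
        nid <- nid + 1L
        nodes[[nid]] <- list(id = nid, x = pos2[1], y = pos2[2], z = pos2[3],
                             role = "interior", pressure = NA_real_,
                             inlet_sao2 = NA_real_)
        sid <- sid + 1L
        rr <- rad_at(depth2) * stats::runif(1, 0.85, 1.15)
        rr <- max(rr, radius_range[1])
        seg_len <- sqrt(sum((pos2 - tp$pos)^2))
        segs[[sid]] <- list(id = sid, from = tp$node, to = nid,
                            radius_um = rr, flow_um3_s = NA_real_,
                            hematocrit = 0.45)
        vol <- vol + pi * rr^2 * seg_len
        new_tips[[length(new_tips) + 1]] <- list(node = nid, pos = pos2,
                                                 dir = d, depth = depth2)
        spawned <- TRUE
      }
      if (!spawned) leaf_nodes <- c(leaf_nodes, tp$node)
    }
    tips <- new_tips
  }
  leaf_nodes <- c(leaf_nodes, vapply(tips, function(tp) tp$node, integer(1)))
  if (length(segs) < 2) return(NULL)
  nodes <- dplyr::bind_rows(lapply(nodes, tibble::as_tibble))
  segs <- dplyr::bind_rows(lapply(segs, tibble::as_tibble))
  # leaves (and any dead-end interior node) become outlets
  deg_out <- table(factor(segs$from, levels = nodes$id))
  is_leaf <- nodes$id %in% leaf_nodes & deg_out[as.character(nodes$id)] == 0 &
    nodes$role != "inlet"
  nodes$role[is_leaf] <- "outlet"
  # drop isolated nodes
  used <- unique(c(segs$from, segs$to))
  nodes <- nodes[nodes$id %in% used, ]
  if (!any(nodes$role == "outlet") || !any(nodes$role == "inlet")) return(NULL)
  vessel_network(nodes, segs, box)
}
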