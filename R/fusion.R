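#' Virtual imaging voxel grid
#'
#' Cubic voxel grid superimposed on the tissue domain, with half-open
#' voxels `[origin + (i-1) L, origin + i L)`. A translation `offset`
#' (each component in `(-L/2, L/2)`) shifts the grid; the grid always
#' covers the whole domain box.
#'
#' @param domain_box `2 x 3` matrix (lo; hi), µm.
#' @param L Voxel edge (µm).
#' @param offset Length-3 translation (µm), components within
#'   `(-L/2, L/2)`.
#' @return A `voxel_grid`: `origin`, `L`, `dims`, `offset`, `domain_box`.
#' @export
make_voxel_grid <- function(domain_box, L, offset = c(0, 0, 0)) {
  if (L <= 0) stop("make_voxel_grid: L must be > 0.", call. = FALSE)
  if (any(abs(offset) >= L / 2)) {
    stop("make_voxel_grid: |offset| components must be < L/2.",
         call. = FALSE)
  }
  domain_box <- as.matrix(domain_box)
  lo <- domain_box[1, ]
  hi <- domain_box[2, ]
  origin <- lo + offset - ifelse(offset > 0, L, 0)
  dims <- as.integer(ceiling((hi - origin) / L - 1e-12))
  structure(list(origin = origin, L = L, dims = dims, offset = offset,
                 domain_box = domain_box),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> L = %g um, %d x %d x %d voxels, offset (%g, %g, %g)\n",
              x$L, x$dims[1], x$dims[2], x$dims[3],
              x$offset[1], x$offset[2], x$offset[3]))
  invisible(x)
}

voxel_box <- function(grid, i, j, k) {
  lo <- grid$origin + (c(i, j, k) - 1) * grid$L
  rbind(lo, lo + grid$L)
}

# Fraction of a voxel's volume lying inside the domain box.
voxel_tissue_fraction <- function(grid, i, j, k) {
  b <- voxel_box(grid, i, j, k)
  lo <- pmax(b[1, ], grid$domain_box[1, ])
  hi <- pmin(b[2, ], grid$domain_box[2, ])
  prod(pmax(hi - lo, 0)) / grid$L^3
}

#' Average the reference lattice field into voxels (GPO2)
#'
#' Per voxel, the mean of LPO2 over the in-domain lattice points whose
#' position falls in the half-open voxel box; voxels containing no
#' lattice point are flagged invalid.
#'
#' @param lattice A solved [tissue_lattice()] (LPO2 filled).
#' @param grid A [make_voxel_grid()].
#' @return List with arrays `gpo2` (mmHg, NA where invalid) and `n_points`.
#' @export
average_gpo2 <- function(lattice, grid) {
  if (all(is.na(lattice$lpo2))) {
    stop("average_gpo2: lattice has no LPO2; run the reference solver.",
         call. = FALSE)
  }
  pts <- lattice_points_matrix(lattice)
  ok <- as.vector(lattice$in_domain)
  pts <- pts[ok, , drop = FALSE]
  vals <- as.vector(lattice$lpo2)[ok]
  vi <- floor((pts[, 1] - grid$origin[1]) / grid$L) + 1
  vj <- floor((pts[, 2] - grid$origin[2]) / grid$L) + 1
  vk <- floor((pts[, 3] - grid$origin[3]) / grid$L) + 1
  keep <- vi >= 1 & vi <= grid$dims[1] & vj >= 1 & vj <= grid$dims[2] &
    vk >= 1 & vk <= grid$dims[3]
  if (!any(keep)) {
    stop("average_gpo2: no lattice points fall inside the grid; ",
         "disjoint coordinate frames?", call. = FALSE)
  }
  lin <- vi[keep] + grid$dims[1] * ((vj[keep] - 1) +
                                      grid$dims[2] * (vk[keep] - 1))
  sums <- rowsum(vals[keep], lin)
  cnts <- rowsum(rep(1, sum(keep)), lin)
  gpo2 <- array(NA_real_, grid$dims)
  npt <- array(0L, grid$dims)
  ii <- as.integer(rownames(sums))
  gpo2[ii] <- sums / cnts
  npt[ii] <- as.integer(cnts)
  list(gpo2 = gpo2, n_points = npt)
}

#' Effective per-voxel fusion inputs from the vascular architecture
#'
#' Derives, for every voxel of `grid`, the quantities a functional imaging
#' study would measure: fractional vascular volume
#' `fvv = sum(clip volumes) / L^3`, effective radius
#' `rc_eff = L sqrt(fvv / pi)` (the radius of a single voxel-spanning
#' vessel of equal volume), effective perfusion
#' `F_eff = sum(Q_i len_i) / (L * L^3)` (path-length-weighted flow per
#' voxel volume, exact for a single spanning vessel), the volume-weighted
#' vessel saturation `SaO2 = sum(SaO2_i vol_i) / V`, the inlet pressure
#' `P_in` via the inverse Hill curve, and the slope factor `m` at `P_in`.
#' Segment saturation inside a voxel is the mean over the blood
#' subsegment values whose midpoints fall in the voxel (segment mean as
#' fallback).
#'
#' @param ref A `reference_field` from [solve_reference_field()].
#' @param grid A [make_voxel_grid()].
#' @return Tibble, one row per voxel: `ix, iy, iz, fvv, rc_eff, F_eff,
#'   sao2, P_in, m, tissue_frac, valid`.
#' @export
effective_voxel_inputs <- function(ref, grid) {
  net <- ref$net
  segs <- net$segments
  src <- ref$sources
  L <- grid$L
  a <- node_xyz(net, segs$from)
  b <- node_xyz(net, segs$to)
  # voxel membership of blood subsegment midpoints
  sv <- cbind(floor((src$x - grid$origin[1]) / L),
              floor((src$y - grid$origin[2]) / L),
              floor((src$z - grid$origin[3]) / L)) + 1
  src_key <- paste(sv[, 1], sv[, 2], sv[, 3], src$segment)
  sao2_by_key <- tapply(src$sao2, src_key, mean)
  seg_mean_sao2 <- tapply(src$sao2, src$segment, mean)
  # clip each segment against candidate voxels along its bounding box
  rows <- list()
  nr <- 0L
  for (s in seq_len(nrow(segs))) {
    pl <- pmin(a[s, ], b[s, ])
    ph <- pmax(a[s, ], b[s, ])
    i0 <- pmax(floor((pl - grid$origin) / L) + 1, 1)
    i1 <- pmin(floor((ph - grid$origin) / L) + 1, grid$dims)
    if (any(i0 > i1)) next
    for (i in i0[1]:i1[1]) for (j in i0[2]:i1[2]) for (k in i0[3]:i1[3]) {
      cl <- clip_segment_to_box(net, s, voxel_box(grid, i, j, k))
      if (cl$length <= 0) next
      key <- paste(i, j, k, segs$id[s])
      sa <- sao2_by_key[key]
      if (is.na(sa)) sa <- seg_mean_sao2[as.character(segs$id[s])]
      nr <- nr + 1L
      rows[[nr]] <- c(i, j, k, cl$length, cl$volume,
                      abs(segs$flow_um3_s[s]) * cl$length, sa)
    }
  }
  empty <- tidyr::expand_grid(ix = seq_len(grid$dims[1]),
                              iy = seq_len(grid$dims[2]),
                              iz = seq_len(grid$dims[3]))
  if (nr == 0L) {
    out <- dplyr::mutate(empty, fvv = 0, rc_eff = NA_real_, F_eff = 0,
                         sao2 = NA_real_, P_in = NA_real_, m = NA_real_,
                         valid = FALSE)
  } else {
    m <- do.call(rbind, rows)
    tab <- tibble::tibble(ix = m[, 1], iy = m[, 2], iz = m[, 3],
                          len = m[, 4], vol = m[, 5], flowlen = m[, 6],
                          sao2_seg = m[, 7])
    agg <- tab |>
      dplyr::group_by(.data$ix, .data$iy, .data$iz) |>
      dplyr::summarise(
        fvv = sum(.data$vol) / L^3,
        F_eff = sum(.data$flowlen) / (L * L^3),
        sao2 = sum(.data$sao2_seg * .data$vol) / sum(.data$vol),
        .groups = "drop"
      )
    out <- empty |>
      dplyr::left_join(agg, by = c("ix", "iy", "iz")) |>
      dplyr::mutate(
        fvv = dplyr::coalesce(.data$fvv, 0),
        F_eff = dplyr::coalesce(.data$F_eff, 0),
        valid = .data$fvv > 0,
        rc_eff = ifelse(.data$valid, L * sqrt(.data$fvv / pi), NA_real_),
        P_in = ifelse(.data$valid,
                      hill_inverse(pmin(.data$sao2, 1 - 1e-12), ref$params),
                      NA_real_),
        m = ifelse(.data$valid, hill_slope_m(pmax(.data$P_in, 1e-6),
                                             ref$params), NA_real_)
      )
  }
  out$tissue_frac <- mapply(function(i, j, k)
    voxel_tissue_fraction(grid, i, j, k), out$ix, out$iy, out$iz)
  dplyr::select(out, "ix", "iy", "iz", "fvv", "rc_eff", "F_eff", "sao2",
                "P_in", "m", "tissue_frac", "valid")
}

#' Run the image-fusion pipeline on one voxel grid
#'
#' Computes, per voxel: the reference GPO2 (lattice average) and the
#' fusion-model MPO2 ([mvif_voxel_average()] on the effective inputs).
#'
#' @param ref A `reference_field`.
#' @param grid A [make_voxel_grid()], or a voxel edge length (µm) from
#'   which an untranslated grid over the reference domain is built.
#' @param couple_mm Passed to [mvif_voxel_average()].
#' @return An `oxygen_maps` object: `grid`, arrays `gpo2`, `mpo2`,
#'   `valid`, and the per-voxel tibble `voxels`.
#' @export
run_fusion <- function(ref, grid, couple_mm = TRUE) {
  if (is.numeric(grid)) {
    grid <- make_voxel_grid(ref$net$domain_box, grid)
  }
  ga <- average_gpo2(ref$lattice, grid)
  vi <- effective_voxel_inputs(ref, grid)
  n <- nrow(vi)
  mpo2 <- rep(NA_real_, n)
  mval <- rep(NA_real_, n)
  clamped <- rep(NA, n)
  for (r in seq_len(n)) {
    if (!vi$valid[r]) next
    inp <- mvif_inputs(P_in = vi$P_in[r], F_perf = vi$F_eff[r],
                       rc = vi$rc_eff[r], L = grid$L, m = vi$m[r],
                       params = ref$params)
    res <- mvif_voxel_average(inp, couple_mm = couple_mm)
    mpo2[r] <- res$mpo2
    mval[r] <- res$M
    clamped[r] <- res$clamped
  }
  vi$mpo2 <- mpo2
  vi$M <- mval
  vi$clamped <- clamped
  lin <- vi$ix + grid$dims[1] * ((vi$iy - 1) + grid$dims[2] * (vi$iz - 1))
  vi$gpo2 <- as.vector(ga$gpo2)[lin]
  vi$n_lattice <- as.vector(ga$n_points)[lin]
  if (!any(vi$valid)) {
    warning("run_fusion: no voxel contains a vessel; empty scatter.",
            call. = FALSE)
  }
  mparr <- array(NA_real_, grid$dims)
  mparr[lin] <- vi$mpo2
  varr <- array(FALSE, grid$dims)
  varr[lin] <- vi$valid
  structure(list(grid = grid, gpo2 = ga$gpo2, mpo2 = mparr, valid = varr,
                 voxels = vi, params = ref$params),
            class = "oxygen_maps")
}

#' @export
print.oxygen_maps <- function(x, ...) {
  v <- dplyr::filter(x$voxels, .data$valid & is.finite(.data$gpo2))
  cat(sprintf("<oxygen_maps> L = %g um, %d voxels (%d valid)\n",
              x$grid$L, nrow(x$voxels), sum(x$voxels$valid)))
  if (nrow(v)) {
    cat(sprintf("  GPO2 mean %.2f, MPO2 mean %.2f mmHg over paired voxels\n",
                mean(v$gpo2), mean(v$mpo2)))
  }
  invisible(x)
}

#' Per-voxel scatter table of an oxygen map
#' @param x An `oxygen_maps`.
#' @param ... Unused.
#' @return The per-voxel tibble (`voxels`).
#' @export
as_tibble.oxygen_maps <- function(x, ...) x$voxels

#' Pooled MPO2/GPO2 scatter over random grid translations
#'
#' Re-runs the fusion at `n_offsets` grid placements: the untranslated
#' grid first (by convention), then translations drawn uniformly from
#' `(-L/2, L/2)^3` with a seeded RNG. Mirrors the accumulation of scatter
#' points at coarse imaging resolutions, where a single grid placement
#' yields few voxels.
#'
#' @param ref A `reference_field`.
#' @param L Voxel edge (µm).
#' @param n_offsets Number of grid placements (>= 1).
#' @param seed RNG seed for the offsets.
#' @param couple_mm Passed to [run_fusion()].
#' @return Tibble: per-voxel rows from every placement, with `offset_id`
#'   (1 = untranslated) and offset components.
#' @export
grid_translation_ensemble <- function(ref, L, n_offsets = 1, seed = 1,
                                      couple_mm = TRUE) {
  if (n_offsets < 1) stop("grid_translation_ensemble: n_offsets >= 1.",
                          call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  offs <- matrix(0, n_offsets, 3)
  if (n_offsets > 1) {
    offs[-1, ] <- stats::runif(3 * (n_offsets - 1), -L / 2, L / 2) *
      0.999 # keep strictly inside the bound
  }
  purrr::map_dfr(seq_len(n_offsets), function(o) {
    g <- make_voxel_grid(ref$net$domain_box, L, offs[o, ])
    maps <- run_fusion(ref, g, couple_mm = couple_mm)
    dplyr::mutate(maps$voxels, offset_id = o,
                  off_x = offs[o, 1], off_y = offs[o, 2], off_z = offs[o, 3])
  })
}
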