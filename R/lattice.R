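#' Tissue lattice for the reference oxygen field
#'
#' A cubic lattice of tissue points covering the network domain (plus an
#' optional surrounding tissue margin) on which the reference solver
#' evaluates pO2 (LPO2). Points are node-centred: coordinates
#' `origin + (i - 1) * h` along each axis, inclusive of both ends.
#'
#' @param net A [vessel_network()] (the lattice covers its `domain_box`).
#' @param h Lattice spacing (µm); 15 µm by default.
#' @param margin Tissue margin (µm) added on every side of the domain box.
#'   The imaged vascular domain sits in surrounding tissue that also
#'   consumes oxygen; the margin captures the diffusion halo so that the
#'   steady-state release/consumption balance closes inside the lattice.
#' @return A `tissue_lattice`: origin, spacing `h`, `dims`, point coordinate
#'   vectors `xs`, `ys`, `zs`, logical `in_domain` array, and `lpo2` array
#'   (NA until solved).
#' @export
tissue_lattice <- function(net, h = 15, margin = 0) {
  if (h <= 0) stop("tissue_lattice: h must be > 0.", call. = FALSE)
  lo <- net$domain_box[1, ] - margin
  hi <- net$domain_box[2, ] + margin
  dims <- pmax(floor((hi - lo) / h + 1e-9), 1) + 1
  axes <- lapply(1:3, function(k) lo[k] + h * (seq_len(dims[k]) - 1))
  ind <- function(k) {
    v <- axes[[k]]
    v >= net$domain_box[1, k] - 1e-9 & v <= net$domain_box[2, k] + 1e-9
  }
  in_dom <- outer(outer(ind(1), ind(2), "&"), ind(3), "&")
  structure(list(origin = lo, h = h, dims = as.integer(dims),
                 xs = axes[[1]], ys = axes[[2]], zs = axes[[3]],
                 in_domain = in_dom,
                 lpo2 = array(NA_real_, dims)),
            class = "tissue_lattice")
}

#' @export
print.tissue_lattice <- function(x, ...) {
  cat(sprintf("<tissue_lattice> %d x %d x %d points, h = %g um\n",
              x$dims[1], x$dims[2], x$dims[3], x$h))
  if (!all(is.na(x$lpo2))) {
    cat(sprintf("  LPO2: mean %.2f, range [%.2f, %.2f] mmHg\n",
                mean(x$lpo2), min(x$lpo2), max(x$lpo2)))
  }
  invisible(x)
}

#' Lattice points as a long tibble
#' @param x A [tissue_lattice()].
#' @param ... Unused.
#' @return Tibble with `i, j, k, x, y, z, in_domain, lpo2`.
#' @export
as_tibble.tissue_lattice <- function(x, ...) {
  g <- expand.grid(i = seq_len(x$dims[1]), j = seq_len(x$dims[2]),
                   k = seq_len(x$dims[3]))
  xx <- x$xs[g$i]
  yy <- x$ys[g$j]
  zz <- x$zs[g$k]
  ind <- as.vector(x$in_domain)
  lp <- as.vector(x$lpo2)
  tibble::tibble(
    i = g$i, j = g$j, k = g$k,
    x = xx, y = yy, z = zz,
    in_domain = ind,
    lpo2 = lp
  )
}

lattice_points_matrix <- function(lat) {
  g <- expand.grid(i = seq_len(lat$dims[1]), j = seq_len(lat$dims[2]),
                   k = seq_len(lat$dims[3]))
  cbind(lat$xs[g$i], lat$ys[g$j], lat$zs[g$k])
}

#' Discretize a network into lattice and subsegment oxygen sources
#'
#' Each vessel segment is split into `ceil(length / ds)` equal subsegments;
#' the midpoint of each subsegment is the oxygen source location used by
#' the Green's-function solver.
#'
#' @param net A [vessel_network()].
#' @param h Lattice spacing (µm).
#' @param ds Target subsegment length (µm); 50 µm by default.
#' @param margin Tissue margin passed to [tissue_lattice()].
#' @return List with `lattice` (a [tissue_lattice()]) and `sources`
#'   (tibble: `segment`, `sub`, `x0..z0`, `x1..z1`, midpoint `x,y,z`,
#'   `ds`, `radius_um`, `q`).
#' @export
discretize <- function(net, h = 15, ds = 50, margin = 0) {
  if (h <= 0 || ds <= 0) stop("discretize: h and ds must be > 0.",
                              call. = FALSE)
  if (!nrow(net$segments)) stop("discretize: empty network.", call. = FALSE)
  lat <- tissue_lattice(net, h = h, margin = margin)
  segs <- net$segments
  a <- node_xyz(net, segs$from)
  b <- node_xyz(net, segs$to)
  len <- segment_lengths(net)
  src <- purrr::map_dfr(seq_len(nrow(segs)), function(i) {
    n_sub <- max(1L, ceiling(len[i] / ds - 1e-12))
    tfrac <- (seq_len(n_sub) - 0.5) / n_sub
    t0 <- (seq_len(n_sub) - 1) / n_sub
    t1 <- seq_len(n_sub) / n_sub
    tibble::tibble(
      segment = segs$id[i], sub = seq_len(n_sub),
      x0 = a[i, 1] + t0 * (b[i, 1] - a[i, 1]),
      y0 = a[i, 2] + t0 * (b[i, 2] - a[i, 2]),
      z0 = a[i, 3] + t0 * (b[i, 3] - a[i, 3]),
      x1 = a[i, 1] + t1 * (b[i, 1] - a[i, 1]),
      y1 = a[i, 2] + t1 * (b[i, 2] - a[i, 2]),
      z1 = a[i, 3] + t1 * (b[i, 3] - a[i, 3]),
      x = a[i, 1] + tfrac * (b[i, 1] - a[i, 1]),
      y = a[i, 2] + tfrac * (b[i, 2] - a[i, 2]),
      z = a[i, 3] + tfrac * (b[i, 3] - a[i, 3]),
      ds = len[i] / n_sub,
      radius_um = segs$radius_um[i],
      q = 0
    )
  })
  list(lattice = lat, sources = src)
}

# Potential (per unit total strength) of a uniform finite line source,
# kernel 1 / (4 pi D alpha r), at points `pts` (n x 3). `rho_min`
# regularizes the perpendicular distance.
line_source_potential <- function(pts, p0, p1, D_alpha, rho_min) {
  d <- p1 - p0
  ell <- sqrt(sum(d^2))
  u <- d / ell
  rel <- sweep(pts, 2, p0)
  proj <- rel %*% u
  rho2 <- rowSums(rel^2) - proj^2
  rho <- sqrt(pmax(rho2, 0))
  rho <- pmax(rho, rho_min)
  s1 <- -proj
  s2 <- ell - proj
  r1 <- sqrt(rho^2 + s1^2)
  r2 <- sqrt(rho^2 + s2^2)
  val <- log((s2 + r2) / (s1 + r1))
  as.numeric(val) / (4 * pi * D_alpha * ell)
}

# Trilinear interpolation of a 3D lattice array at points (n x 3).
trilinear_at <- function(lat, arr, pts) {
  h <- lat$h
  fx <- (pts[, 1] - lat$origin[1]) / h
  fy <- (pts[, 2] - lat$origin[2]) / h
  fz <- (pts[, 3] - lat$origin[3]) / h
  d <- lat$dims
  i0 <- pmin(pmax(floor(fx), 0), d[1] - 2)
  j0 <- pmin(pmax(floor(fy), 0), d[2] - 2)
  k0 <- pmin(pmax(floor(fz), 0), d[3] - 2)
  tx <- pmin(pmax(fx - i0, 0), 1)
  ty <- pmin(pmax(fy - j0, 0), 1)
  tz <- pmin(pmax(fz - k0, 0), 1)
  at <- function(di, dj, dk) {
    arr[cbind(i0 + di + 1, j0 + dj + 1, k0 + dk + 1)]
  }
  (1 - tx) * (1 - ty) * (1 - tz) * at(0, 0, 0) +
    tx * (1 - ty) * (1 - tz) * at(1, 0, 0) +
    (1 - tx) * ty * (1 - tz) * at(0, 1, 0) +
    tx * ty * (1 - tz) * at(1, 1, 0) +
    (1 - tx) * (1 - ty) * tz * at(0, 0, 1) +
    tx * (1 - ty) * tz * at(1, 0, 1) +
    (1 - tx) * ty * tz * at(0, 1, 1) +
    tx * ty * tz * at(1, 1, 1)
}

# FFT convolution operator mapping lattice point sink strengths
# (uM um^3/s) to their potential contribution at every lattice point,
# kernel 1 / (4 pi D alpha max(r, h/2)). Returns a closure.
make_sink_convolver <- function(lat, D_alpha) {
  d <- lat$dims
  h <- lat$h
  # pad to 2,3,5-smooth sizes: R's mixed-radix FFT is slow on large primes
  nf <- vapply(2 * d - 1, function(n) stats::nextn(n, c(2, 3, 5)),
               numeric(1))
  off <- lapply(1:3, function(k) {
    v <- numeric(nf[k])
    v[seq_len(d[k])] <- 0:(d[k] - 1)
    v[nf[k] + 1 - seq_len(d[k] - 1)] <- -(1:(d[k] - 1))
    v * h
  })
  r2 <- outer(outer(off[[1]]^2, off[[2]]^2, "+"), off[[3]]^2, "+")
  r <- sqrt(r2)
  K <- 1 / (4 * pi * D_alpha * pmax(r, h / 2))
  fK <- stats::fft(K)
  pad <- array(0, nf)
  function(c_arr) {
    pad[] <- 0
    pad[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- c_arr
    out <- stats::fft(stats::fft(pad) * fK, inverse = TRUE) / prod(nf)
    Re(out[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])])
  }
}
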