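#' Built-in study fixtures
#'
#' Solved vessel networks for the four standard study conditions:
#' \describe{
#'   \item{krogh}{One straight vessel spanning a 120 µm cube of tissue --
#'     the analytic single-vessel geometry, sized so one capillary fully
#'     oxygenates the voxel (the regime where the Krogh solution holds).}
#'   \item{parallel}{A parallel capillary bed at 50 µm spacing (a typical
#'     inter-capillary distance) with per-vessel heterogeneity in radius
#'     and flow and a smooth spatial gradient of inlet saturation
#'     (capillaries fed by shared arterioles carry correlated inputs).
#'     A 6 x 6 array is generated but the measured domain is the interior
#'     200 x 200 x 200 µm block around the central 4 x 4 vessels: the
#'     outer vessel ring and the axial continuations are guard bands that
#'     supply the surrounding tissue, so the interior behaves like a
#'     periodic, well-supplied bed (normal tissue at imaging
#'     resolution).}
#'   \item{tumor}{Stochastic tortuous branching trees in a
#'     990 x 810 x 150 µm window-chamber-sized slab, rescaled to a total
#'     inflow of 230.37 nL/min.}
#'   \item{brain}{A denser, finer network in a 150 x 160 x 140 µm block
#'     with total inflow 10.8 nL/min and the higher brain consumption
#'     rate.}
#' }
#'
#' @param preset Fixture name.
#' @param seed RNG seed for the stochastic generators.
#' @return A [vessel_network()] with flows solved.
#' @export
study_fixture <- function(preset = c("krogh", "parallel", "tumor", "brain"),
                          seed = 1) {
  preset <- match.arg(preset)
  switch(preset,
    krogh = generate_single_vessel(
      length = 120, radius = 5, flow = 2e5, inlet_sao2 = 0.9,
      domain_box = rbind(c(0, 0, 0), c(120, 120, 120))),
    parallel = {
      net <- generate_parallel_array(
        n_vessels = 36, spacing = 50, jitter = 5, length = 280,
        radius_range = c(3.5, 6.5), flow_range = c(5e4, 3e5),
        inlet_sao2 = function(x, y) {
          pmin(0.95, pmax(0.6, 0.62 + 0.3 * (x + y) / 600))
        },
        margin = 25, seed = seed)
      # vessels run z in [10, 290]; measured block: central 4 x 4 vessels,
      # inner 200 um of depth
      net$nodes$z <- net$nodes$z + 10
      net$domain_box <- rbind(c(50, 50, 50), c(250, 250, 250))
      dimnames(net$domain_box) <- list(c("lo", "hi"), c("x", "y", "z"))
      net
    },
    tumor = solve_hemodynamics(
      generate_tumor_like_network(seed = seed),
      target_inflow = 230.37 * 1e6 / 60),
    brain = solve_hemodynamics(
      generate_tumor_like_network(
        domain_box = rbind(c(0, 0, 0), c(150, 160, 140)),
        target_vascular_fraction = 0.03, n_roots = 2, step = 25,
        branch_prob = 0.35, radius_range = c(2.5, 6), tortuosity = 0.4,
        inlet_sao2 = 0.95, seed = seed),
      target_inflow = 10.8 * 1e6 / 60)
  )
}

#' Study configuration
#'
#' Collects every knob of the end-to-end validation study in one place.
#' Defaults follow the study conditions: 15 µm reference lattice, 50 µm
#' subsegments, a 75 µm surrounding tissue margin, voxel sizes 50-300 µm
#' in 50 µm steps for the tumor (50 and 100 µm only for the small brain
#' block), five random grid translations for voxel sizes of 200 µm and
#' above, and hypoxic-fraction ladders of 2.5-15 mmHg (tumor) or
#' 16-22 mmHg (brain).
#'
#' @param preset Fixture preset (see [study_fixture()]).
#' @param seed Master seed for generation, grid translation and error
#'   propagation.
#' @param voxel_sizes Voxel edge lengths (µm).
#' @param h,ds,margin Reference-solver discretization (µm). The default
#'   margin (75 µm) covers the oxygenation halo; the parallel preset uses
#'   150 µm so the margin also clears its guard vessel ring.
#' @param n_offsets_coarse Grid translations for voxel sizes >= 200 µm.
#' @param ref_tol Reference-solver residual tolerance (mmHg). The regular
#'   fixtures resolve to 0.01 mmHg; the stochastic tree networks use
#'   0.75 mmHg because a few wall-collocation rows at branch points
#'   retain residuals of that order (the field elsewhere is much more
#'   accurate).
#' @param hf_thresholds Hypoxic-fraction threshold ladder (mmHg).
#' @param sensitivity_voxel,error_voxel Voxel size (µm) for the
#'   sensitivity scan and the error-propagation study.
#' @param error_fwhm,error_replicates Error-propagation settings.
#' @param out_dir Optional output directory for CSV/JSON result files.
#' @return A `study_config` list.
#' @export
study_config <- function(preset = "tumor", seed = 1,
                         voxel_sizes = NULL, h = 15, ds = 50, margin = NULL,
                         n_offsets_coarse = 5,
                         ref_tol = NULL,
                         hf_thresholds = NULL,
                         sensitivity_voxel = 150, error_voxel = 150,
                         error_fwhm = 0.20, error_replicates = 10,
                         out_dir = NULL) {
  if (is.null(voxel_sizes)) {
    voxel_sizes <- switch(preset,
      brain = c(50, 100),
      krogh = 120,
      seq(50, 300, by = 50))
  }
  if (is.null(margin)) {
    margin <- if (identical(preset, "parallel")) 150 else 75
  }
  if (is.null(ref_tol)) {
    ref_tol <- if (preset %in% c("tumor", "brain")) 0.75 else 0.01
  }
  if (is.null(hf_thresholds)) {
    hf_thresholds <- if (identical(preset, "brain")) seq(16, 22, by = 2)
                     else seq(2.5, 15, by = 2.5)
  }
  structure(list(
    preset = preset, seed = seed, voxel_sizes = voxel_sizes,
    h = h, ds = ds, margin = margin,
    n_offsets_coarse = n_offsets_coarse, ref_tol = ref_tol,
    hf_thresholds = hf_thresholds,
    sensitivity_voxel = sensitivity_voxel, error_voxel = error_voxel,
    error_fwhm = error_fwhm, error_replicates = error_replicates,
    out_dir = out_dir
  ), class = "study_config")
}

#' Run the full validation study
#'
#' Executes the whole pipeline for one configuration:
#' generate fixture -> reference solve -> fusion at each voxel size
#' (pooling random grid translations at coarse sizes) -> MPO2-vs-GPO2
#' regression, hypoxic-fraction regression, nearest-neighbor correction
#' at the smallest voxel size, sensitivity scan and Gaussian error
#' propagation. Deterministic for a fixed config (same seed, same
#' outputs).
#'
#' @param config A [study_config()].
#' @return List of class `study_result`: `config`, `net`, `ref`
#'   (reference field), `maps` (per voxel size), `scatter` (pooled
#'   tibble), `regressions` (glance table per voxel size), `hf`
#'   (HF regressions), `nn` (regression after nearest-neighbor
#'   correction at the smallest voxel size), `sensitivity`,
#'   `error_propagation`.
#' @export
run_study <- function(config = study_config()) {
  cfg <- config
  params <- physiology_params(if (identical(cfg$preset, "brain")) "brain"
                              else "tumor")
  net <- study_fixture(cfg$preset, seed = cfg$seed)
  ref <- solve_reference_field(net, params = params, h = cfg$h, ds = cfg$ds,
                               margin = cfg$margin, tol = cfg$ref_tol)
  maps <- list()
  scatter <- list()
  regs <- list()
  hfs <- list()
  for (L in cfg$voxel_sizes) {
    n_off <- if (L >= 200) cfg$n_offsets_coarse else 1
    sc <- grid_translation_ensemble(ref, L, n_offsets = n_off,
                                    seed = cfg$seed)
    key <- as.character(L)
    scatter[[key]] <- dplyr::mutate(sc, voxel_size = L)
    maps[[key]] <- run_fusion(ref, make_voxel_grid(net$domain_box, L))
    reg <- tryCatch(linear_regression(sc), error = function(e) NULL)
    if (!is.null(reg)) {
      regs[[key]] <- dplyr::mutate(glance(reg), voxel_size = L)
    }
    hf <- tryCatch(hf_correlation(sc, cfg$hf_thresholds),
                   error = function(e) NULL)
    if (!is.null(hf)) {
      hfs[[key]] <- dplyr::mutate(glance(hf), voxel_size = L)
    }
  }
  L_min <- min(cfg$voxel_sizes)
  nn_maps <- nearest_neighbor_correction(maps[[as.character(L_min)]])
  nn_reg <- tryCatch(linear_regression(nn_maps$voxels),
                     error = function(e) NULL)
  sens <- err <- NULL
  Ls <- as.character(cfg$sensitivity_voxel)
  if (Ls %in% names(maps)) {
    sens <- sensitivity_scan(maps[[Ls]])
  }
  Le <- as.character(cfg$error_voxel)
  if (Le %in% names(maps)) {
    err <- gaussian_error_propagation(maps[[Le]], target = "F",
                                      fwhm_fraction = cfg$error_fwhm,
                                      n_replicates = cfg$error_replicates,
                                      seed = cfg$seed)
  }
  out <- structure(list(
    config = cfg, net = net, ref = ref, maps = maps,
    scatter = dplyr::bind_rows(scatter),
    regressions = dplyr::bind_rows(regs),
    hf = dplyr::bind_rows(hfs),
    nn = if (!is.null(nn_reg)) glance(nn_reg) else NULL,
    nn_maps = nn_maps,
    sensitivity = sens,
    error_propagation = err
  ), class = "study_result")
  if (!is.null(cfg$out_dir)) write_study(out, cfg$out_dir)
  out
}

#' @export
print.study_result <- function(x, ...) {
  cat("<study_result> preset:", x$config$preset, "\n")
  cat("MPO2 ~ GPO2 regression by voxel size:\n")
  print(as.data.frame(x$regressions), digits = 3)
  invisible(x)
}

write_study <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(res$scatter, file.path(dir, "scatter.csv"))
  readr::write_csv(res$regressions, file.path(dir, "regressions.csv"))
  if (nrow(res$hf)) readr::write_csv(res$hf, file.path(dir, "hf.csv"))
  if (!is.null(res$sensitivity)) {
    readr::write_csv(res$sensitivity, file.path(dir, "sensitivity.csv"))
  }
  summary <- list(
    preset = res$config$preset, seed = res$config$seed,
    voxel_sizes = res$config$voxel_sizes,
    balance_error = res$ref$diagnostics$balance_error,
    nn_r_squared = if (!is.null(res$nn)) res$nn$r.squared else NULL,
    average_cv = if (!is.null(res$error_propagation))
      res$error_propagation$average_cv else NULL
  )
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Interior RMS difference between two reference fields
#'
#' Root-mean-square LPO2 difference over in-domain lattice points at
#' least `exclude_radius` from every vessel axis -- the standard
#' cross-check between the superposition solver and the
#' finite-difference oracle (near-vessel points are excluded because the
#' two discretizations represent the sub-lattice singular field
#' differently).
#'
#' @param ref_a,ref_b `reference_field` objects on the same lattice
#'   geometry.
#' @param exclude_radius Exclusion distance from vessel axes (µm);
#'   default two lattice spacings.
#' @return RMS difference (mmHg).
#' @export
field_rms <- function(ref_a, ref_b, exclude_radius = 2 * ref_a$lattice$h) {
  la <- ref_a$lattice
  lb <- ref_b$lattice
  if (!all(la$dims == lb$dims) || la$h != lb$h) {
    stop("field_rms: lattices differ; re-solve on a common geometry.",
         call. = FALSE)
  }
  pts <- lattice_points_matrix(la)
  keep <- as.vector(la$in_domain)
  src <- ref_a$sources
  dmin <- rep(Inf, nrow(pts))
  for (j in seq_len(nrow(src))) {
    p0 <- c(src$x0[j], src$y0[j], src$z0[j])
    p1 <- c(src$x1[j], src$y1[j], src$z1[j])
    d <- p1 - p0
    ell2 <- sum(d^2)
    t <- pmin(pmax(sweep(pts, 2, p0) %*% d / ell2, 0), 1)
    prj <- cbind(p0[1] + t * d[1], p0[2] + t * d[2], p0[3] + t * d[3])
    dmin <- pmin(dmin, sqrt(rowSums((pts - prj)^2)))
  }
  keep <- keep & dmin >= exclude_radius
  sqrt(mean((as.vector(la$lpo2)[keep] - as.vector(lb$lpo2)[keep])^2))
}
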