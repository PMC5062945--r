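#' Ordinary least-squares regression of MPO2 on GPO2
#'
#' Unweighted simple linear regression of the fusion-model voxel pO2
#' against the reference voxel pO2, with the Pearson correlation and its
#' two-sided p-value.
#'
#' @param scatter Data frame with numeric columns `mpo2` and `gpo2`
#'   (e.g. the `voxels` table of an `oxygen_maps`, or a pooled
#'   [grid_translation_ensemble()] table). Rows with missing values are
#'   dropped.
#' @return An `mvif_regression` object (see [tidy.mvif_regression()]):
#'   slope, intercept (mmHg), r_squared, pearson_r, p_value, n_points.
#' @export
linear_regression <- function(scatter) {
  d <- dplyr::filter(scatter, is.finite(.data$mpo2), is.finite(.data$gpo2))
  if (nrow(d) < 3) {
    stop("linear_regression: need at least 3 valid MPO2/GPO2 pairs.",
         call. = FALSE)
  }
  if (stats::var(d$gpo2) == 0) {
    stop("linear_regression: GPO2 has zero variance.", call. = FALSE)
  }
  fit <- stats::lm(mpo2 ~ gpo2, data = d)
  # a constant response yields a zero-sd warning and an NA correlation
  ct <- suppressWarnings(stats::cor.test(d$gpo2, d$mpo2))
  structure(list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r_squared = summary(fit)$r.squared,
    pearson_r = unname(ct$estimate),
    p_value = ct$p.value,
    n_points = nrow(d),
    model = fit
  ), class = "mvif_regression")
}

#' @export
print.mvif_regression <- function(x, ...) {
  cat(sprintf(
    "<mvif_regression> slope %.3f, intercept %.2f mmHg, r^2 %.3f (R %.3f, p %.3g, n %d)\n",
    x$slope, x$intercept, x$r_squared, x$pearson_r, x$p_value, x$n_points))
  invisible(x)
}

#' Hypoxic fraction of an oxygen map
#'
#' Fraction of valid voxels with pO2 strictly below `threshold`. Voxels
#' whose model value was clamped to zero count as hypoxic.
#'
#' @param map An `oxygen_maps`, or a numeric vector/array of voxel pO2
#'   (NA = invalid).
#' @param threshold Threshold(s) in mmHg; vectorized.
#' @param which For an `oxygen_maps`: `"mpo2"` or `"gpo2"`.
#' @return Hypoxic fraction(s) in \[0, 1\], named by threshold when
#'   several are given.
#' @export
hypoxic_fraction <- function(map, threshold, which = c("mpo2", "gpo2")) {
  if (inherits(map, "oxygen_maps")) {
    which <- match.arg(which)
    v <- map$voxels
    vals <- v[[which]][v$valid & is.finite(v[[which]])]
  } else {
    vals <- map[is.finite(map)]
  }
  if (!length(vals)) stop("hypoxic_fraction: no valid voxels.",
                          call. = FALSE)
  out <- vapply(threshold, function(th) mean(vals < th), numeric(1))
  if (length(threshold) > 1) names(out) <- threshold
  out
}

#' Hypoxic-fraction correlation between the fusion model and the reference
#'
#' Computes the hypoxic fraction of the MPO2 and GPO2 maps over a ladder
#' of thresholds and regresses HF(MPO2) on HF(GPO2). Tumor studies use
#' thresholds 2.5-15 mmHg in 2.5 steps; well-oxygenated (brain-like)
#' tissue uses 16-22 mmHg in 2 steps.
#'
#' @param maps An `oxygen_maps` (or a data frame with `mpo2`/`gpo2`
#'   voxel columns).
#' @param thresholds Numeric ladder (>= 3 values).
#' @return An `mvif_regression` over the HF pairs, with the HF table in
#'   `$hf_table`.
#' @export
hf_correlation <- function(maps, thresholds = seq(2.5, 15, by = 2.5)) {
  if (length(thresholds) < 3) {
    stop("hf_correlation: need >= 3 thresholds for a regression.",
         call. = FALSE)
  }
  v <- if (inherits(maps, "oxygen_maps")) maps$voxels else maps
  v <- dplyr::filter(v, is.finite(.data$mpo2), is.finite(.data$gpo2))
  hf_m <- vapply(thresholds, function(th) mean(v$mpo2 < th), numeric(1))
  hf_g <- vapply(thresholds, function(th) mean(v$gpo2 < th), numeric(1))
  if (stats::var(hf_g) == 0 && stats::var(hf_m) == 0) {
    stop("hf_correlation: degenerate ladder (all HF identical).",
         call. = FALSE)
  }
  reg <- linear_regression(tibble::tibble(mpo2 = hf_m, gpo2 = hf_g))
  reg$hf_table <- tibble::tibble(threshold = thresholds, hf_mpo2 = hf_m,
                                 hf_gpo2 = hf_g)
  reg
}

#' Nearest-neighbor correction of an MPO2 map
#'
#' Compensates for oxygen diffusing in from vessels in adjacent voxels at
#' fine grid resolutions. In `"augment"` mode (default) each voxel's value
#' is averaged together with its existing face-adjacent (up to 6) valid
#' neighbors; in `"replace"` mode the neighbors' mean replaces the voxel
#' value outright. With `fill_invalid = TRUE`, voxels without vasculature
#' are additionally assigned the mean of their valid neighbors and join
#' the valid set.
#'
#' @param maps An `oxygen_maps`.
#' @param mode `"augment"` or `"replace"`.
#' @param fill_invalid Fill vessel-free voxels from their neighbors
#'   (default `FALSE`).
#' @return A new `oxygen_maps` with corrected `mpo2` (array and `voxels`
#'   table).
#' @export
nearest_neighbor_correction <- function(maps, mode = c("augment", "replace"),
                                        fill_invalid = FALSE) {
  mode <- match.arg(mode)
  arr <- maps$mpo2
  d <- dim(arr)
  ok <- is.finite(arr)
  vals <- ifelse(ok, arr, 0)
  nsum <- array(0, d)
  ncnt <- array(0, d)
  # vectorized 6-neighbor accumulation via sub-array assignment
  add_dir <- function(ax, by) {
    ito <- lapply(d, seq_len)
    ifr <- lapply(d, seq_len)
    if (by == 1) {
      ito[[ax]] <- 1:(d[ax] - 1); ifr[[ax]] <- 2:d[ax]
    } else {
      ito[[ax]] <- 2:d[ax]; ifr[[ax]] <- 1:(d[ax] - 1)
    }
    vsub <- do.call(`[`, c(list(vals), ifr, list(drop = FALSE)))
    osub <- do.call(`[`, c(list(ok), ifr, list(drop = FALSE)))
    nsum_sub <- do.call(`[`, c(list(nsum), ito, list(drop = FALSE))) + vsub
    ncnt_sub <- do.call(`[`, c(list(ncnt), ito, list(drop = FALSE))) + osub
    nsum <<- do.call(`[<-`, c(list(nsum), ito, list(nsum_sub)))
    ncnt <<- do.call(`[<-`, c(list(ncnt), ito, list(ncnt_sub)))
  }
  for (ax in 1:3) if (d[ax] > 1) { add_dir(ax, 1); add_dir(ax, -1) }
  corrected <- arr
  has_nb <- ncnt > 0
  if (mode == "replace") {
    corrected[has_nb & ok] <- nsum[has_nb & ok] / ncnt[has_nb & ok]
  } else {
    corrected[has_nb & ok] <- (nsum[has_nb & ok] + arr[has_nb & ok]) /
      (ncnt[has_nb & ok] + 1)
  }
  filled <- array(FALSE, d)
  if (fill_invalid) {
    filled <- has_nb & !ok
    corrected[filled] <- nsum[filled] / ncnt[filled]
  }
  maps$mpo2 <- corrected
  maps$valid <- maps$valid | filled
  lin <- maps$voxels$ix + d[1] * ((maps$voxels$iy - 1) +
                                    d[2] * (maps$voxels$iz - 1))
  maps$voxels$mpo2 <- as.vector(corrected)[lin]
  maps$voxels$valid <- maps$voxels$valid | as.vector(filled)[lin]
  maps
}

#' Sensitivity of the fusion model to its vascular inputs
#'
#' One-at-a-time scan: each input is scaled by -20, -10, +10 and +20 %
#' from its reference value and the percent change of the mean MPO2 over
#' valid voxels is recorded. Scanned inputs: effective vessel radius
#' `rc`, perfusion `F`, maximum consumption `M0`, vessel saturation
#' `SaO2` (re-clipped to <= 1, flagged), and hemoglobin concentration
#' `CtHb` (scales the bound-oxygen capacity C' and hence the slope
#' factor m).
#'
#' @param maps An `oxygen_maps` from [run_fusion()].
#' @param inputs Character vector of inputs to scan.
#' @param factors Scale factors (1.0 is the reference by construction).
#' @param couple_mm Passed to [mvif_voxel_average()].
#' @return A tibble of class `sensitivity_table`: `input`, `factor`,
#'   `mean_mpo2`, `percent_deviation`, `sao2_clipped`.
#' @export
sensitivity_scan <- function(maps,
                             inputs = c("rc", "F", "M0", "SaO2", "CtHb"),
                             factors = c(0.8, 0.9, 1.1, 1.2),
                             couple_mm = TRUE) {
  v <- dplyr::filter(maps$voxels, .data$valid, is.finite(.data$mpo2))
  L <- maps$grid$L
  params <- maps$params
  ref_mean <- mean(recompute_mpo2(v, L, params, couple_mm = couple_mm))
  out <- purrr::map_dfr(inputs, function(inp) {
    purrr::map_dfr(factors, function(f) {
      vv <- v
      pp <- params
      clipped <- FALSE
      if (inp == "rc") {
        vv$rc_eff <- vv$rc_eff * f
      } else if (inp == "F") {
        vv$F_eff <- vv$F_eff * f
      } else if (inp == "M0") {
        pp <- modify_params(pp, M0 = pp$M0 * f)
      } else if (inp == "SaO2") {
        s <- vv$sao2 * f
        clipped <- any(s > 0.99)
        # physiological ceiling: saturations are re-clipped at 0.99 so the
        # inverse Hill transform stays on the arterial pressure scale
        s <- pmin(s, 0.99)
        vv$sao2 <- s
        vv$P_in <- hill_inverse(s, pp)
        vv$m <- hill_slope_m(pmax(vv$P_in, 1e-6), pp)
      } else if (inp == "CtHb") {
        pp <- modify_params(pp, C_prime = pp$C_prime * f)
        vv$m <- hill_slope_m(pmax(vv$P_in, 1e-6), pp)
      } else {
        stop("sensitivity_scan: unknown input '", inp, "'", call. = FALSE)
      }
      mm <- mean(recompute_mpo2(vv, L, pp, couple_mm = couple_mm))
      tibble::tibble(input = inp, factor = f, mean_mpo2 = mm,
                     percent_deviation = 100 * (mm - ref_mean) / ref_mean,
                     sao2_clipped = clipped)
    })
  })
  class(out) <- c("sensitivity_table", class(out))
  attr(out, "reference_mean") <- ref_mean
  out
}

modify_params <- function(p, ...) {
  ch <- list(...)
  for (nm in names(ch)) p[[nm]] <- ch[[nm]]
  p
}

# Recompute MPO2 for rows of a voxel-inputs table (valid rows only).
recompute_mpo2 <- function(v, L, params, couple_mm = TRUE) {
  vapply(seq_len(nrow(v)), function(r) {
    inp <- mvif_inputs(P_in = v$P_in[r], F_perf = v$F_eff[r],
                       rc = v$rc_eff[r], L = L, m = v$m[r], params = params)
    mvif_voxel_average(inp, couple_mm = couple_mm)$mpo2
  }, numeric(1))
}

#' Gaussian measurement-error propagation through the fusion model
#'
#' Emulates imaging measurement noise: per voxel, `n_replicates` mock
#' values of the target input are drawn from a Gaussian centred on the
#' measured value with FWHM equal to `fwhm_fraction` of that value
#' (sigma = FWHM / sqrt(8 ln 2)); MPO2 is recomputed for each draw.
#' Non-positive draws are redrawn (at most 100 retries). Per-voxel
#' replicate streams derive deterministically from `(seed, voxel)` so
#' results do not depend on evaluation order.
#'
#' @param maps An `oxygen_maps`.
#' @param target `"F"` (perfusion) or `"fvv"` (fractional vascular
#'   volume; perturbing it rescales the effective radius).
#' @param fwhm_fraction Gaussian FWHM as a fraction of the voxel value.
#' @param n_replicates Draws per voxel (>= 2).
#' @param seed Master seed.
#' @param couple_mm Passed to [mvif_voxel_average()].
#' @return List of class `error_propagation`: `voxels` tibble (per-voxel
#'   `mean`, `sd`, `se`, `cv`), `average_cv`, `n_replicates`, `seed`,
#'   `target`, `fwhm_fraction`.
#' @export
gaussian_error_propagation <- function(maps, target = c("F", "fvv"),
                                       fwhm_fraction = 0.20,
                                       n_replicates = 10, seed = 1,
                                       couple_mm = TRUE) {
  target <- match.arg(target)
  if (n_replicates < 2) {
    stop("gaussian_error_propagation: need n_replicates >= 2.",
         call. = FALSE)
  }
  v <- dplyr::filter(maps$voxels, .data$valid, is.finite(.data$mpo2))
  L <- maps$grid$L
  params <- maps$params
  sig_scale <- fwhm_fraction / sqrt(8 * log(2))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  draw_for_voxel <- function(value, voxel_key) {
    set.seed((seed * 1000003L + voxel_key) %% .Machine$integer.max)
    if (sig_scale == 0) return(rep(value, n_replicates))
    out <- stats::rnorm(n_replicates, value, sig_scale * value)
    tries <- 0
    while (any(out <= 0) && tries < 100) {
      bad <- out <= 0
      out[bad] <- stats::rnorm(sum(bad), value, sig_scale * value)
      tries <- tries + 1
    }
    if (any(out <= 0)) {
      stop("gaussian_error_propagation: could not draw positive values.",
           call. = FALSE)
    }
    out
  }
  res <- purrr::map_dfr(seq_len(nrow(v)), function(r) {
    key <- v$ix[r] + 10000L * v$iy[r] + 1000000L * v$iz[r]
    base <- if (target == "F") v$F_eff[r] else v$fvv[r]
    draws <- draw_for_voxel(base, key)
    mp <- vapply(draws, function(dval) {
      F_eff <- if (target == "F") dval else v$F_eff[r]
      rc <- if (target == "fvv") L * sqrt(dval / pi) else v$rc_eff[r]
      rc <- min(rc, L / sqrt(pi) * 0.999)
      inp <- mvif_inputs(P_in = v$P_in[r], F_perf = F_eff, rc = rc, L = L,
                         m = v$m[r], params = params)
      mvif_voxel_average(inp, couple_mm = couple_mm)$mpo2
    }, numeric(1))
    tibble::tibble(ix = v$ix[r], iy = v$iy[r], iz = v$iz[r],
                   gpo2 = v$gpo2[r],
                   mean = mean(mp), sd = stats::sd(mp),
                   se = stats::sd(mp) / sqrt(n_replicates),
                   cv = ifelse(mean(mp) > 0, stats::sd(mp) / mean(mp), NA))
  })
  structure(list(
    voxels = res,
    average_cv = mean(res$cv, na.rm = TRUE),
    n_replicates = n_replicates, seed = seed, target = target,
    fwhm_fraction = fwhm_fraction
  ), class = "error_propagation")
}

#' @export
print.error_propagation <- function(x, ...) {
  cat(sprintf(
    "<error_propagation> target %s, FWHM %.0f%%, %d replicates: average CV %.1f%%\n",
    x$target, 100 * x$fwhm_fraction, x$n_replicates, 100 * x$average_cv))
  invisible(x)
}
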