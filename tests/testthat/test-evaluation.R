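test_that("regression recovers exact linear relations", {
  d <- tibble::tibble(gpo2 = c(1, 5, 9, 14, 22), mpo2 = gpo2)
  r <- linear_regression(d)
  expect_equal(r$slope, 1)
  expect_equal(r$intercept, 0, tolerance = 1e-12)
  expect_equal(r$r_squared, 1)
  d2 <- dplyr::mutate(d, mpo2 = 2 * gpo2 + 3)
  r2 <- linear_regression(d2)
  expect_equal(r2$slope, 2)
  expect_equal(r2$intercept, 3)
  expect_equal(r2$r_squared, r2$pearson_r^2, tolerance = 1e-12)
  expect_error(linear_regression(d[1:2, ]), "at least 3")
  expect_error(linear_regression(tibble::tibble(gpo2 = rep(2, 5),
                                                mpo2 = 1:5)), "variance")
  td <- tidy(r2)
  expect_equal(td$estimate, c(3, 2))
  expect_equal(glance(r2)$n, 5)
})

test_that("hypoxic fraction counts voxels strictly below threshold", {
  m <- c(1, 3, 6, 12)
  expect_equal(hypoxic_fraction(m, 5), 0.5)
  expect_equal(hypoxic_fraction(m, 0.5), 0)
  expect_equal(hypoxic_fraction(m, 100), 1)
  ladder <- hypoxic_fraction(m, seq(2.5, 15, by = 2.5))
  expect_true(all(diff(ladder) >= 0))
  expect_error(hypoxic_fraction(rep(NA_real_, 3), 5), "no valid")
})

test_that("HF regression of identical maps is the identity", {
  set.seed(1)
  v <- tibble::tibble(gpo2 = runif(60, 0, 30), mpo2 = gpo2)
  r <- hf_correlation(v, seq(2.5, 15, by = 2.5))
  expect_equal(r$slope, 1)
  expect_equal(r$r_squared, 1)
  expect_equal(nrow(r$hf_table), 6)
  expect_error(hf_correlation(v, c(5)), ">= 3 thresholds")
  # uniform negative shift in the model map: slope stays near 1 with a
  # positive HF offset
  v2 <- dplyr::mutate(v, mpo2 = pmax(gpo2 - 2, 0))
  r2 <- hf_correlation(v2, seq(2.5, 15, by = 2.5))
  expect_gt(r2$intercept, 0)
  expect_equal(r2$slope, 1, tolerance = 0.35)
})

test_that("nearest-neighbor correction follows the edge rules", {
  grid <- make_voxel_grid(rbind(c(0, 0, 0), c(150, 150, 150)), 50)
  mk <- function(arr) {
    v <- tidyr::expand_grid(ix = 1:3, iy = 1:3, iz = 1:3)
    lin <- v$ix + 3 * ((v$iy - 1) + 3 * (v$iz - 1))
    v$mpo2 <- as.vector(arr)[lin]
    v$valid <- is.finite(v$mpo2)
    structure(list(grid = grid, mpo2 = arr, gpo2 = arr,
                   valid = is.finite(arr), voxels = v,
                   params = physiology_params()),
              class = "oxygen_maps")
  }
  uni <- mk(array(7, c(3, 3, 3)))
  for (mode in c("replace", "augment")) {
    out <- nearest_neighbor_correction(uni, mode = mode)
    expect_equal(out$mpo2, uni$mpo2)
  }
  centred <- array(12, c(3, 3, 3))
  centred[2, 2, 2] <- 0
  out <- nearest_neighbor_correction(mk(centred), mode = "replace")
  expect_equal(out$mpo2[2, 2, 2], 12)     # replaced by its six neighbors
  out_a <- nearest_neighbor_correction(mk(centred), mode = "augment")
  expect_equal(out_a$mpo2[2, 2, 2], 72 / 7)
  # corner voxel averages only its three existing neighbors
  expect_equal(out$mpo2[1, 1, 1],
               mean(c(centred[2, 1, 1], centred[1, 2, 1], centred[1, 1, 2])))
  # invalid voxels are only filled on request
  holey <- centred
  holey[3, 3, 3] <- NA
  out_n <- nearest_neighbor_correction(mk(holey))
  expect_true(is.na(out_n$mpo2[3, 3, 3]))
  out_f <- nearest_neighbor_correction(mk(holey), fill_invalid = TRUE)
  expect_equal(out_f$mpo2[3, 3, 3], 12)
})

test_that("sensitivity scan is anchored at zero and directionally correct", {
  maps <- tumor_maps(150)
  sens <- sensitivity_scan(maps, factors = c(0.8, 1.0, 1.2))
  anchor <- dplyr::filter(sens, .data$factor == 1)
  expect_true(all(abs(anchor$percent_deviation) < 1e-9))
  dev <- function(i, f) {
    dplyr::filter(sens, .data$input == i, .data$factor == f)$percent_deviation
  }
  expect_lt(dev("M0", 1.2), 0)
  expect_gt(dev("F", 1.2), 0)
  expect_gt(dev("SaO2", 1.2), 0)
  expect_gt(dev("CtHb", 1.2), 0)
  expect_gt(abs(dev("M0", 1.2)), abs(dev("rc", 1.2)) * 0.999)
})

test_that("error propagation is seeded, scaled and guarded", {
  maps <- tumor_maps(150)
  e0 <- gaussian_error_propagation(maps, "F", fwhm_fraction = 0,
                                   n_replicates = 5, seed = 3)
  expect_true(all(e0$voxels$cv == 0 | is.na(e0$voxels$cv)))
  # FWHM/sigma identity
  expect_equal(0.2 / sqrt(8 * log(2)), 0.0849, tolerance = 1e-3)
  e1 <- gaussian_error_propagation(maps, "F", 0.2, 10, seed = 9)
  e2 <- gaussian_error_propagation(maps, "F", 0.2, 10, seed = 9)
  expect_equal(e1$voxels, e2$voxels)
  expect_true(is.finite(e1$average_cv) && e1$average_cv > 0)
  expect_error(gaussian_error_propagation(maps, "F", 0.2, n_replicates = 1),
               "n_replicates")
  expect_equal(glance(e1)$average_cv, e1$average_cv)
})
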