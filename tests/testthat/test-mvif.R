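tumor_inputs <- function(P_in = 51, F_perf = 0.059, rc = 5, L = 150,
                         M = NULL, params = physiology_params()) {
  m <- hill_slope_m(P_in, params)
  if (is.null(M)) M <- params$M0
  mvif_inputs(P_in = P_in, F_perf = F_perf, rc = rc, L = L, m = m,
              params = params, M = M)
}

test_that("radial form factor matches the Krogh-Erlang closed form", {
  expect_identical(form_factor_g1(5, 5, 50), 0)
  expect_equal(form_factor_g1(50, 5, 50), 2500 * log(10) - 1237.5,
               tolerance = 1e-12)
  # sealed outer boundary: dG1/dr -> 0 at rT
  eps <- 1e-5
  dG <- (form_factor_g1(50, 5, 50) - form_factor_g1(50 - eps, 5, 50)) / eps
  expect_lt(abs(dG), 1e-3)
  expect_error(form_factor_g1(60, 5, 50), "r must lie")
  # cross-check against direct integration of the radial Krogh ODE
  p <- physiology_params()
  drop_ode <- function(r_eval, rc, rT) {
    # D alpha (1/r) d/dr(r dP/dr) = M, zero flux at rT
    integrand <- function(r) (p$M0 * p$H / (2 * p$D)) * (rT^2 / r - r)
    stats::integrate(integrand, rc, r_eval, rel.tol = 1e-10)$value
  }
  a1 <- p$M0 * p$H / (2 * p$D)
  for (r in c(15, 30, 50)) {
    expect_equal(a1 * form_factor_g1(r, 5, 50), drop_ode(r, 5, 50),
                 tolerance = 1e-8)
  }
})

test_that("axial form factor is the linear mass-balance solution", {
  expect_identical(form_factor_g2(0, 5, 50, 150), 0)
  expect_equal(form_factor_g2(75, 5, 50, 150), 0.5 * (1 - 0.01))
  expect_equal(form_factor_g2(150, 5, 5000, 150), 1, tolerance = 1e-5)
  expect_error(form_factor_g2(200, 5, 50, 150), "z must lie")
})

test_that("pointwise model honours its boundary anchors", {
  p <- physiology_params()
  inp <- tumor_inputs()
  expect_equal(mvif_pointwise(inp$rc, 0, inp), inp$P_in,
               ignore_attr = TRUE)
  inp0 <- tumor_inputs(M = 0)
  expect_equal(mvif_pointwise(40, 80, inp0), inp0$P_in, ignore_attr = TRUE)
  # printed radial drop: wall -> rT at fixed z with tumor constants
  drop <- p$M0 * p$H / (2 * p$D) * form_factor_g1(50, 5, 50)
  expect_equal(drop, 14.93, tolerance = 1e-3)
  expect_error(mvif_pointwise(10, 10, tumor_inputs(F_perf = 0)),
               "perfusion-limited")
})

test_that("voxel average reduces to the closed form and its limits", {
  p <- physiology_params()
  inp0 <- tumor_inputs(M = 0)
  expect_equal(mvif_voxel_average(inp0, couple_mm = FALSE)$mpo2, inp0$P_in)
  # as F -> Inf the advection term vanishes exactly
  inp_inf <- tumor_inputs(P_in = 80, F_perf = 1e12, L = 100)
  a1 <- p$M0 * p$H / (2 * p$D)
  g1b <- oxyfuse:::g1_annulus_mean(inp_inf$rc, inp_inf$rT)
  expect_equal(mvif_voxel_average(inp_inf, couple_mm = FALSE)$mpo2,
               80 - a1 * g1b, tolerance = 1e-9)
  # doubling F halves the advection term (clamp inactive, M fixed)
  i1 <- tumor_inputs(P_in = 80, F_perf = 0.06, L = 100)
  i2 <- tumor_inputs(P_in = 80, F_perf = 0.12, L = 100)
  g2b <- (1 - i1$rc^2 / i1$rT^2) / 2
  adv1 <- p$M0 * p$H / ((1 + i1$m) * 0.06) * g2b
  expect_equal(mvif_voxel_average(i2, couple_mm = FALSE)$mpo2 -
                 mvif_voxel_average(i1, couple_mm = FALSE)$mpo2,
               adv1 / 2, tolerance = 1e-9)
})

test_that("quadrature of the clamped field matches the analytic average", {
  # unclamped case: quadrature and closed form agree to 1e-6 relative
  inp <- tumor_inputs(P_in = 80, F_perf = 0.06, L = 100)
  closed <- mvif_voxel_average(inp, couple_mm = FALSE)$mpo2
  # force the quadrature path by integrating the raw pointwise field
  gq <- oxyfuse:::gauss_legendre(48)
  r <- inp$rc + (inp$rT - inp$rc) * gq$x
  z <- inp$L * gq$x
  vals <- outer(r, z, function(r, z) mvif_pointwise(r, z, inp))
  wr <- gq$w * (inp$rT - inp$rc) * r
  num <- as.numeric(wr %*% vals %*% (gq$w * inp$L))
  expect_equal(num / (sum(wr) * sum(gq$w * inp$L)), closed,
               tolerance = 1e-6)
})

test_that("voxel average is monotone in its physiological drivers", {
  base <- mvif_voxel_average(tumor_inputs())$mpo2
  expect_lte(base, 51) # never exceeds the inlet pressure
  hiM <- physiology_params(M0 = 25, M0_unit = "uM_per_s")
  expect_lt(mvif_voxel_average(tumor_inputs(params = hiM))$mpo2, base)
  expect_gt(mvif_voxel_average(tumor_inputs(F_perf = 0.2))$mpo2, base)
  expect_gt(mvif_voxel_average(tumor_inputs(P_in = 60))$mpo2, base)
  expect_lt(mvif_voxel_average(tumor_inputs(P_in = 40))$mpo2, base)
})

test_that("degenerate voxels are flagged, not computed", {
  p <- physiology_params()
  expect_error(mvif_inputs(P_in = 40, F_perf = 0.05, rc = 100, L = 150,
                           m = 50, params = p), "rc < rT")
  inp <- tumor_inputs()
  inp$F_perf <- 0
  res <- mvif_voxel_average(inp)
  expect_true(is.na(res$mpo2))
})
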