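test_that("discretization follows the equal-division and lattice rules", {
  net <- generate_single_vessel(length = 120, radius = 5,
    domain_box = rbind(c(0, 0, 0), c(150, 150, 150)))
  dd <- discretize(net, h = 15, ds = 50, margin = 0)
  expect_equal(dd$lattice$dims, c(11L, 11L, 11L)) # inclusive 15-um grid
  expect_equal(nrow(dd$sources), 3)               # ceil(120/50)
  expect_equal(unique(dd$sources$ds), 40)         # equal parts
  expect_equal(sum(dd$sources$ds), 120)
  long <- generate_single_vessel(length = 150, radius = 5)
  dd2 <- discretize(long, ds = 50, margin = 0)
  expect_equal(sum(dd2$sources$ds), 150)
  expect_error(discretize(vessel_network(net$nodes[0, ], net$segments[0, ],
                                         net$domain_box)), "empty|missing")
})

test_that("finite-difference point source matches the screened kernel", {
  # a point source in a uniform linear sink k has the Yukawa field
  # exp(-r/l)/(4 pi D alpha r) with l = sqrt(D alpha / k); l = 60 um keeps
  # the field negligible at the sealed walls of a 300 um box
  p <- physiology_params()
  net <- generate_single_vessel(length = 30, radius = 5,
    domain_box = rbind(c(0, 0, 0), c(300, 300, 300)))
  lat <- tissue_lattice(net, h = 7.5, margin = 0)
  src <- array(0, lat$dims)
  ctr <- (lat$dims + 1) %/% 2
  src[ctr[1], ctr[2], ctr[3]] <- 1e6
  k <- 0.75
  P <- fd_diffusion_solve(lat, src, k = k, params = p, tol = 1e-9)
  D_alpha <- p$D / p$H
  ell <- sqrt(D_alpha / k)
  for (off in c(4, 6, 8, 10)) {
    r <- off * 7.5
    expected <- 1e6 * exp(-r / ell) / (4 * pi * D_alpha * r)
    expect_equal(P[ctr[1] + off, ctr[2], ctr[3]], expected,
                 tolerance = 0.08)
  }
})

test_that("a sealed box with net source and no sink is flagged unsolvable", {
  p <- physiology_params()
  net <- generate_single_vessel()
  lat <- tissue_lattice(net, h = 15, margin = 0)
  src <- array(1, lat$dims)
  expect_error(fd_diffusion_solve(lat, src, k = 0, params = p),
               "no steady solution")
})

test_that("the finite-difference field is symmetric about a centred vessel", {
  fd <- krogh_fd_sealed()
  P <- fd$lattice$lpo2
  d <- dim(P)
  expect_equal(P, P[d[1]:1, , ], tolerance = 1e-6)
  expect_equal(P, P[, d[2]:1, ], tolerance = 1e-6)
})

test_that("release is consumption-controlled: low demand, flat blood pO2", {
  # in the sealed oracle, a 10x lower consumption rate shrinks both the
  # release and the axial blood pO2 decline by about as much
  net <- krogh_net()
  full <- krogh_fd_sealed()
  plow <- physiology_params(M0 = 1.7857, M0_unit = "uM_per_s")
  low <- fd_oracle(net, params = plow, margin = 0)
  drop_full <- max(full$sources$blood_po2) - min(full$sources$blood_po2)
  drop_low <- max(low$sources$blood_po2) - min(low$sources$blood_po2)
  expect_lt(drop_low, 0.25 * drop_full)
  expect_lt(sum(low$sources$q), 0.2 * sum(full$sources$q))
})

test_that("raising consumption never raises the tissue field", {
  net <- krogh_net()
  lo <- solve_reference_field(net)
  hi <- solve_reference_field(net,
    params = physiology_params(M0 = 25, M0_unit = "uM_per_s"))
  expect_true(all(hi$lattice$lpo2 <= lo$lattice$lpo2 + 0.05))
})

test_that("blood pO2 is non-increasing along the flow direction", {
  ref <- krogh_ref()
  expect_true(all(diff(ref$sources$blood_po2) <= 1e-9))
  expect_true(all(ref$sources$q >= 0))
})

test_that("voxel averaging of the lattice field follows the half-open rule", {
  net <- krogh_net()
  ref <- krogh_ref()
  g1 <- make_voxel_grid(net$domain_box, 120)
  ga <- average_gpo2(ref$lattice, g1)
  tb <- as_tibble(ref$lattice)
  inside <- tb$in_domain & tb$x < 120 & tb$y < 120 & tb$z < 120
  expect_equal(ga$gpo2[1, 1, 1], mean(tb$lpo2[inside]), tolerance = 1e-12)
  expect_equal(sum(ga$n_points), sum(inside))
  far <- make_voxel_grid(rbind(c(5000, 5000, 5000), c(5200, 5200, 5200)), 100)
  expect_error(average_gpo2(ref$lattice, far), "disjoint")
})
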