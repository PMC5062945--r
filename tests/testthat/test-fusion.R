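test_that("voxel grids cover the domain under the counting convention", {
  g <- make_voxel_grid(rbind(c(0, 0, 0), c(990, 810, 150)), 200)
  expect_equal(g$dims, c(5L, 5L, 1L))   # ceil(990/200) with partial 5th
  expect_error(make_voxel_grid(rbind(c(0, 0, 0), c(990, 810, 150)), 150,
                               offset = c(80, 0, 0)), "offset")
  g2 <- make_voxel_grid(rbind(c(0, 0, 0), c(990, 810, 150)), 150,
                        offset = c(70, 0, 0))
  expect_s3_class(g2, "voxel_grid")
  # half-open rule: a point exactly on a voxel boundary joins the upper one
  gi <- make_voxel_grid(rbind(c(0, 0, 0), c(300, 300, 300)), 100)
  expect_equal(floor((100 - gi$origin[1]) / gi$L) + 1, 2)
})

test_that("effective inputs use the volume-weighted saturation formula", {
  # two segments with (vol 2, SaO2 0.8) and (vol 3, SaO2 0.6) -> 0.68
  expect_equal(sum(c(0.8, 0.6) * c(2, 3)) / 5, 0.68)
  ref <- krogh_ref()
  grid <- make_voxel_grid(krogh_net()$domain_box, 120)
  vi <- effective_voxel_inputs(ref, grid)
  expect_equal(nrow(vi), 1)
  # a single spanning vessel reproduces its radius and flow exactly
  expect_equal(vi$rc_eff, 5, tolerance = 1e-9)
  expect_equal(vi$F_eff, 2e5 / 120^3, tolerance = 1e-9)
  expect_equal(vi$fvv, pi * 25 * 120 / 120^3, tolerance = 1e-9)
  # the voxel saturation lies within the contributing subsegment range
  expect_gte(vi$sao2, min(ref$sources$sao2))
  expect_lte(vi$sao2, max(ref$sources$sao2))
  expect_equal(vi$P_in, hill_inverse(vi$sao2, ref$params), tolerance = 1e-9)
})

test_that("voxels without vessels are invalid and empty grids warn", {
  ref <- krogh_ref()
  # a grid offset so the fine corner voxels miss the central vessel
  grid <- make_voxel_grid(krogh_net()$domain_box, 30)
  vi <- effective_voxel_inputs(ref, grid)
  expect_true(any(!vi$valid))
  expect_true(all(is.na(vi$P_in[!vi$valid])))
  maps <- run_fusion(ref, grid)
  expect_true(all(is.na(maps$voxels$mpo2[!maps$voxels$valid])))
})

test_that("fractional vascular volume partitions exactly at any offset", {
  ref <- bed_ref()
  net <- ref$net
  for (off in list(c(0, 0, 0), c(12.5, -20, 5))) {
    g <- make_voxel_grid(net$domain_box, 50, off)
    vi <- effective_voxel_inputs(ref, g)
    # total vessel volume inside the grid's full extent
    gbox <- rbind(g$origin, g$origin + g$dims * g$L)
    total <- vascular_volume(net, box = gbox)
    expect_equal(sum(vi$fvv) * 50^3, total, tolerance = 1e-6 * total)
  }
})

test_that("grid translation ensembles are seeded and bookkept", {
  ref <- krogh_ref()
  a <- grid_translation_ensemble(ref, 60, n_offsets = 3, seed = 42)
  b <- grid_translation_ensemble(ref, 60, n_offsets = 3, seed = 42)
  expect_equal(a, b)
  expect_equal(sort(unique(a$offset_id)), 1:3)
  first <- dplyr::filter(a, .data$offset_id == 1)
  expect_true(all(first$off_x == 0 & first$off_y == 0 & first$off_z == 0))
  expect_true(all(abs(a$off_x) < 30))
  per <- dplyr::count(a, .data$offset_id)
  expect_equal(sum(per$n), nrow(a))
})

test_that("fusion maps align GPO2 and MPO2 on the same voxels", {
  maps <- tumor_maps(150)
  v <- maps$voxels
  expect_equal(nrow(v), prod(maps$grid$dims))
  ok <- v$valid & is.finite(v$gpo2)
  expect_gt(sum(ok), 10)
  expect_true(all(v$mpo2[ok] <= v$P_in[ok] + 1e-9))
  lin <- v$ix + maps$grid$dims[1] * ((v$iy - 1) + maps$grid$dims[2] * (v$iz - 1))
  expect_equal(as.vector(maps$mpo2)[lin], v$mpo2)
})
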