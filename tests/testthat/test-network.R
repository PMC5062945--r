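minimal_net <- function() {
  nodes <- tibble::tibble(
    id = 1:2, x = c(0, 0), y = c(0, 0), z = c(0, 150),
    role = c("inlet", "outlet"), pressure = NA_real_,
    inlet_sao2 = c(0.9, NA))
  segs <- tibble::tibble(id = 1L, from = 1L, to = 2L, radius_um = 5,
                         flow_um3_s = 1e5, hematocrit = 0.45)
  vessel_network(nodes, segs, rbind(c(-75, -75, 0), c(75, 75, 150)))
}

test_that("network validation catches structural errors", {
  net <- minimal_net()
  expect_s3_class(net, "vessel_network")
  bad <- net$segments
  bad$to <- 99L
  expect_error(vessel_network(net$nodes, bad, net$domain_box), "missing nodes")
  bad <- net$segments
  bad$radius_um <- -1
  expect_error(vessel_network(net$nodes, bad, net$domain_box), "radius")
  badn <- net$nodes
  badn$inlet_sao2[1] <- 1.5
  expect_error(vessel_network(badn, net$segments, net$domain_box),
               "inlet_sao2")
})

test_that("write/read round trip preserves a network in both formats", {
  net <- generate_parallel_array(n_vessels = 3, spacing = 60, jitter = 4,
                                 seed = 5)
  for (fmt in c("csv-pair", "json")) {
    path <- if (fmt == "json") withr::local_tempfile(fileext = ".json")
            else withr::local_tempdir()
    write_network(net, path, fmt)
    back <- read_network(path, fmt)
    expect_equal(back$nodes, net$nodes, tolerance = 1e-12)
    expect_equal(back$segments, net$segments, tolerance = 1e-12)
    expect_equal(unname(back$domain_box), unname(net$domain_box))
  }
  expect_error(read_network(file.path(tempdir(), "nope"), "csv-pair"),
               "expected nodes.csv")
})

test_that("segment clipping partitions length over a voxel tiling", {
  net <- generate_tumor_like_network(seed = 3)
  full_box <- net$domain_box
  grid <- make_voxel_grid(full_box, 150)
  for (i in seq_len(min(nrow(net$segments), 40))) {
    total <- clip_segment_to_box(net, i, full_box)$length
    parts <- 0
    for (ix in seq_len(grid$dims[1])) for (iy in seq_len(grid$dims[2]))
      for (iz in seq_len(grid$dims[3])) {
        parts <- parts + clip_segment_to_box(
          net, i, oxyfuse:::voxel_box(grid, ix, iy, iz))$length
      }
    expect_equal(parts, total, tolerance = 1e-9)
  }
})

test_that("clipping handles inside, crossing and outside segments", {
  net <- minimal_net()
  box_all <- rbind(c(-10, -10, -10), c(10, 10, 200))
  expect_equal(clip_segment_to_box(net, 1, box_all)$length, 150)
  box_half <- rbind(c(-10, -10, 0), c(10, 10, 75))
  expect_equal(clip_segment_to_box(net, 1, box_half)$length, 75)
  box_out <- rbind(c(50, 50, 0), c(60, 60, 150))
  expect_identical(clip_segment_to_box(net, 1, box_out)$length, 0)
})

test_that("vascular volume is the cylinder sum", {
  net <- minimal_net()
  expect_equal(vascular_volume(net), pi * 25 * 150, tolerance = 1e-12)
})
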