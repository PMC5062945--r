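test_that("single-vessel fixture has the textbook geometry", {
  net <- generate_single_vessel(length = 150, radius = 5,
                                domain_box = rbind(c(0, 0, 0),
                                                   c(150, 150, 150)))
  expect_equal(vascular_volume(net), pi * 25 * 150, tolerance = 1e-12)
  expect_equal(vascular_volume(net) / 150^3, 0.003490659, tolerance = 1e-6)
  zs <- sort(net$nodes$z)
  expect_equal(zs, c(0, 150))  # inlet/outlet on opposite faces
  expect_setequal(net$nodes$role, c("inlet", "outlet"))
  expect_error(generate_single_vessel(length = 500,
    domain_box = rbind(c(0, 0, 0), c(150, 150, 150))), "fit")
})

test_that("parallel arrays are reproducible and keep their spacing", {
  a <- generate_parallel_array(n_vessels = 4, spacing = 75, jitter = 10,
                               seed = 11)
  b <- generate_parallel_array(n_vessels = 4, spacing = 75, jitter = 10,
                               seed = 11)
  expect_equal(a$nodes, b$nodes)
  expect_equal(a$segments, b$segments)
  noj <- generate_parallel_array(n_vessels = 4, spacing = 75, jitter = 0,
                                 seed = 1)
  xy <- unique(noj$nodes[, c("x", "y")])
  d <- as.matrix(stats::dist(xy))
  expect_equal(min(d[d > 0]), 75)
  expect_error(generate_parallel_array(n_vessels = 4, spacing = 8,
                                       radius_range = c(4, 6)), "spacing")
})

test_that("tumor-like generator meets its vascular fraction and domain", {
  net <- generate_tumor_like_network(seed = 1)
  expect_equal(unname(net$domain_box[2, ] - net$domain_box[1, ]),
               c(990, 810, 150))
  frac <- vascular_volume(net) /
    prod(net$domain_box[2, ] - net$domain_box[1, ])
  expect_gt(frac, 0.02 * 0.8)
  expect_lt(frac, 0.02 * 1.2)
  expect_true(all(net$segments$radius_um >= 3 - 1e-9 &
                  net$segments$radius_um <= 15 * 1.15))
  net2 <- generate_tumor_like_network(seed = 1)
  expect_equal(net$nodes, net2$nodes)
  expect_equal(net$segments, net2$segments)
})

test_that("tumor-like networks span realistic inter-vessel distances", {
  net <- generate_tumor_like_network(seed = 4)
  pos <- as.matrix(net$nodes[, c("x", "y", "z")])
  # nearest-neighbour distances among segment endpoints, as a spacing proxy
  d <- as.matrix(stats::dist(pos))
  diag(d) <- Inf
  nn <- apply(d, 1, min)
  expect_gt(max(nn), 40)   # sparse pockets exist
  expect_lt(min(nn), 30)   # and crowded ones
})
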