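two_node_tube <- function(radius = 5, length = 150) {
  nodes <- tibble::tibble(
    id = 1:2, x = 0, y = 0, z = c(0, length),
    role = c("inlet", "outlet"), pressure = c(60, 20),
    inlet_sao2 = c(0.9, NA))
  segs <- tibble::tibble(id = 1L, from = 1L, to = 2L, radius_um = radius,
                         flow_um3_s = NA_real_, hematocrit = 0.45)
  vessel_network(nodes, segs, rbind(c(-75, -75, 0), c(75, 75, length)))
}

test_that("a single tube recovers the Poiseuille closed form", {
  net <- solve_hemodynamics(two_node_tube(), viscosity = 4)
  mu <- 4 * 7.5006e-6
  expect_equal(net$segments$flow_um3_s,
               pi * 40 * 5^4 / (8 * mu * 150), tolerance = 1e-9)
})

test_that("a symmetric bifurcation splits flow evenly and conserves it", {
  nodes <- tibble::tibble(
    id = 1:4,
    x = c(0, 0, -50, 50), y = 0, z = c(0, 100, 200, 200),
    role = c("inlet", "interior", "outlet", "outlet"),
    pressure = c(60, NA, 20, 20), inlet_sao2 = c(0.9, NA, NA, NA))
  segs <- tibble::tibble(id = 1:3, from = c(1L, 2L, 2L), to = c(2L, 3L, 4L),
                         radius_um = c(6, 4, 4), flow_um3_s = NA_real_,
                         hematocrit = 0.45)
  net <- vessel_network(nodes, segs, rbind(c(-100, -10, 0), c(100, 10, 200)))
  net <- solve_hemodynamics(net)
  expect_equal(net$segments$flow_um3_s[2], net$segments$flow_um3_s[3],
               tolerance = 1e-9)
  expect_equal(net$segments$flow_um3_s[1],
               net$segments$flow_um3_s[2] + net$segments$flow_um3_s[3],
               tolerance = 1e-9)
  fc <- flow_conservation(net)
  expect_true(all(fc$relative < 1e-6))
})

test_that("tree networks conserve flow and honor a target inflow", {
  net <- generate_tumor_like_network(seed = 2)
  net <- solve_hemodynamics(net, target_inflow = 230.37 * 1e6 / 60)
  fc <- flow_conservation(net)
  expect_true(all(fc$relative < 1e-6))
  inl <- net$nodes$id[net$nodes$role == "inlet"]
  inflow <- sum(net$segments$flow_um3_s[net$segments$from %in% inl]) -
    sum(net$segments$flow_um3_s[net$segments$to %in% inl])
  expect_equal(inflow, 230.37 * 1e6 / 60, tolerance = 1e-9)
})

test_that("missing boundary conditions are rejected", {
  net <- two_node_tube()
  net$nodes$role <- c("interior", "interior")
  expect_error(solve_hemodynamics(net), "inlet")
})
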