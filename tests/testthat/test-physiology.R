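test_that("Hill curve hits its anchor points and stays bounded", {
  p <- physiology_params()
  expect_identical(hill_saturation(p$P50, p), 0.5)
  expect_equal(hill_saturation(52, p), 8 / 9, tolerance = 1e-12)
  expect_identical(hill_saturation(0, p), 0)
  P <- seq(0, 300, by = 0.5)
  S <- hill_saturation(P, p)
  expect_true(all(S >= 0 & S <= 1))
  expect_true(all(diff(S) >= 0))
  expect_error(hill_saturation(-1, p), "P must be")
})

test_that("inverse Hill curve round-trips and rejects S = 1", {
  p <- physiology_params()
  expect_equal(hill_inverse(0.5, p), 26)
  expect_equal(hill_inverse(8 / 9, p), 52, tolerance = 1e-9)
  for (P in c(1, 10, 40, 100, 200)) {
    expect_equal(hill_inverse(hill_saturation(P, p), p), P,
                 tolerance = 1e-9)
  }
  expect_identical(hill_inverse(0, p), 0)
  expect_error(hill_inverse(1, p), "unbounded")
})

test_that("dissociation slope factor matches a central finite difference", {
  p <- physiology_params()
  expect_equal(hill_slope_m(p$P50, p), 0.74 * 8800 * 3 / 104,
               tolerance = 1e-12)
  for (P in c(5, 15, 26, 50, 90)) {
    eps <- 1e-4 * P
    num <- p$H * p$C_prime *
      (hill_saturation(P + eps, p) - hill_saturation(P - eps, p)) / (2 * eps)
    expect_equal(hill_slope_m(P, p), num, tolerance = 1e-6)
  }
  expect_lt(hill_slope_m(1e5, p), 1e-6) # saturation plateau
  p0 <- physiology_params(C_prime = 0)
  expect_identical(hill_slope_m(26, p0), 0)
})

test_that("Michaelis-Menten consumption is bounded and half-maximal at Km", {
  p <- physiology_params()
  expect_equal(michaelis_menten_rate(p$Km, p), p$M0 / 2)
  expect_identical(michaelis_menten_rate(0, p), 0)
  expect_equal(michaelis_menten_rate(1e7, p), p$M0, tolerance = 1e-6)
  P <- seq(0, 80, by = 0.25)
  M <- michaelis_menten_rate(P, p)
  expect_true(all(M <= p$M0))
  expect_true(all(diff(M) >= 0))
})

test_that("unit canonicalization converts O2 volume fractions via STP", {
  expect_equal(to_canonical_units(0.0004, "cm3O2_per_cm3_per_s"),
               17.857, tolerance = 1e-4)
  expect_equal(to_canonical_units(0.0025, "cm3O2_per_cm3_per_s"),
               111.607, tolerance = 1e-4)
  expect_identical(to_canonical_units(2000, "um2_per_s"), 2000)
  expect_error(to_canonical_units(1, "furlongs"), "unknown unit")
})

test_that("parameter presets carry the tumor and brain consumption rates", {
  expect_equal(physiology_params("tumor")$M0, 17.857, tolerance = 1e-4)
  expect_equal(physiology_params("brain")$M0, 111.607, tolerance = 1e-4)
  expect_equal(physiology_params()$alpha_blood, 1 / 0.74)
  expect_error(physiology_params(n_hill = 0.5), "n_hill")
})

test_that("blood oxygen content inverts to pressure", {
  p <- physiology_params()
  for (P in c(0.5, 5, 20, 45, 90)) {
    cont <- oxyfuse:::blood_o2_content(P, p)
    expect_equal(oxyfuse:::blood_o2_pressure(cont, p), P, tolerance = 1e-7)
  }
  expect_identical(oxyfuse:::blood_o2_pressure(0, p), 0)
})
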