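test_that("per-level gravity follows the cumulative-mass relation", {
  # two levels with masses 8 and 10 kg: dPtot = 2.1 * 2 = 4.2 kg,
  # dForce = 4.2 * 9.81 = 41.202 N
  gl <- vertebral_level_loads(60, level_mass = c(T1 = 8, T2 = 10))
  expect_equal(gl$ptot, 15 + 2.1 * c(8, 10))
  expect_equal(gl$dptot[2], 4.2)
  expect_equal(gl$force[2], 41.202)
  # equal masses give a zero increment
  gl0 <- vertebral_level_loads(60, level_mass = c(T1 = 8, T2 = 8))
  expect_equal(gl0$force[2], 0)
})

test_that("gravity loads conserve the cumulative mass (summation oracle)", {
  gl <- vertebral_level_loads(42)
  n <- nrow(gl)
  # independent oracle: total = g * (Ptot_n - Ptot_1 + first-level load)
  total_oracle <- 9.81 * (gl$ptot[n] - gl$ptot[1] + gl$ptot[1])
  expect_equal(sum(gl$force), total_oracle, tolerance = 1e-12)
  expect_true(all(diff(gl$ptot) >= 0))
  expect_lte(sum(gl$mass), 42)
})

test_that("invalid gravity inputs are rejected", {
  expect_error(vertebral_level_loads(42, level_mass = c(T1 = -1, T2 = 2)),
               "non-negative")
  expect_error(vertebral_level_loads(10, level_mass = c(T1 = 6, T2 = 7)),
               "exceed")
})

test_that("patch resultants equal pressure times area", {
  geo <- ref_geometry()
  # 0.085 MPa x 47.1 cm^2 -> 400.35 N (the nominal 400 N axillary force)
  p1 <- pressure_patch("left axillary inferior", 0.085, geo)
  expect_equal(p1$force, 400.35)
  expect_lt(abs(p1$force - 400), 1)
  # 0.085 MPa x 23.5 cm^2 -> 199.75 N (the nominal 200 N)
  p2 <- pressure_patch("right axillary inferior", 0.085, geo)
  expect_equal(p2$force, 199.75)
  expect_lt(abs(p2$force - 200), 1)
  # CFEM1 left lumbar: 0.009 MPa x 116 cm^2 -> 104.4 N
  p3 <- pressure_patch("left lumbar", 0.009, geo)
  expect_equal(p3$force, 104.4)
  # directions are unit vectors; vertical patches push +Z
  expect_equal(sum(p1$direction^2), 1, tolerance = 1e-12)
  expect_equal(p1$direction, c(0, 0, 1))
  # dorsolateral -> ventromedial from the left: +X, +Y
  expect_true(all(p3$direction[1] > 0, p3$direction[2] > 0))
})

test_that("pressures above the regional threshold are rejected", {
  geo <- ref_geometry()
  expect_error(pressure_patch("left lumbar", 0.036, geo), "threshold")
  expect_error(pressure_patch("left axillary inferior", 0.086, geo), "threshold")
  expect_error(pressure_patch("nowhere", 0.01, geo), "unknown")
})

test_that("CFEM combinations carry the table pressures", {
  geo <- ref_geometry()
  lum <- vapply(paste0("CFEM", 1:4), function(cs) {
    lc <- brace_load_case(cs, geo)
    lc$patches[[2]]$pressure
  }, 0)
  expect_equal(unname(lum), c(0.009, 0.018, 0.026, 0.035))
  lc4 <- brace_load_case("CFEM4", geo)
  expect_length(lc4$patches, 5)
  for (p in lc4$patches[-2]) {
    expect_equal(p$pressure, if (grepl("inferior", p$region)) 0.085 else 0.035)
  }
  expect_error(brace_load_case("CFEM9", geo), "unknown")
  expect_length(brace_load_case("upright", geo)$patches, 0)
})

test_that("the lumbar-pressure series scales and reduces to CFEM4", {
  geo <- ref_geometry()
  series <- cfem_series(geo)
  expect_equal(vapply(series, function(lc) lc$patches[[2]]$pressure, 0),
               c(0.009, 0.018, 0.026, 0.035))
  one <- cfem_series(geo, fractions = 1)[[1]]
  ref4 <- brace_load_case("CFEM4", geo)
  expect_equal(vapply(one$patches, `[[`, 0, "pressure"),
               vapply(ref4$patches, `[[`, 0, "pressure"))
  half <- cfem_series(geo, max_lumbar_pressure = 0.020, fractions = 0.5)[[1]]
  expect_equal(half$patches[[2]]$pressure, 0.010)
  expect_error(cfem_series(geo, fractions = numeric(0)), "empty")
  expect_error(cfem_series(geo, fractions = c(0.5, 1.2)), "fractions")
})
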