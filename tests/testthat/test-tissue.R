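test_that("a symmetric solved state has exact unit disc ratios", {
  geo <- straight_geometry()
  model <- assemble_model(geo)
  lc <- brace_load_case("upright", geo)
  mf <- optimize_muscle_forces(geo, lc)
  st <- solve_static(model, lc, mf)
  hr <- disc_height_ratio(st, "T6")
  expect_equal(hr$height_ratio, 1, tolerance = 1e-9)
  expect_false(hr$penetration)
  sr <- disc_stress_ratio(st, "T6")
  expect_equal(sr$stress_ratio, 1, tolerance = 1e-9)
  expect_length(sr$concave_points, 10)
  expect_length(sr$convex_points, 10)
})

test_that("height ratio matches the wedge formula when one endplate tilts", {
  geo <- straight_geometry()
  model <- assemble_model(geo)
  st <- solve_static(model, list(label = "none", gravity = NULL, patches = list()))
  # impose a small coronal wedge on the deformed state and recompute
  gamma <- spinebrace:::deg2rad(2)
  n <- length(geo$vertebrae)
  th <- matrix(0, n, 3); u <- matrix(0, n, 3)
  i6 <- match("T6", vapply(geo$vertebrae, `[[`, "", "level"))
  th[i6, 2] <- gamma   # rotate T6 about +Y
  st$deformed <- deform_geometry(geo, u, th)
  hr <- disc_height_ratio(st, "T6")
  dsc <- geo$discs[[i6]]
  # wedge opens one lateral margin by ~ a * gamma relative to the other
  h_conc <- hr$height_concave; h_conv <- hr$height_convex
  expect_equal(abs(h_conc - h_conv), 2 * dsc$a * tan(gamma) / 1, tolerance = 0.05)
  expect_equal(hr$height_ratio, h_conc / h_conv)
})

test_that("point stresses reproduce the closed-form beam solution", {
  r <- 12
  disc <- list(upper_level = "T1", lower_level = "T2", center = c(0, 0, 0),
               R = diag(3), height = 5, a = r, b = r, nucleus_fraction = 0.4,
               annulus = "annulus fibrosus", nucleus = "nucleus pulposus")
  Ix <- pi / 4 * r^4
  # pure sagittal bending: sigma = Mx y / Ix at every sampled point
  w <- list(N = 0, Mx = 5000, My = 0, T = 0)
  pts <- spinebrace:::side_sample_points(r, r, 1, npts = 10, arc_deg = 120)
  s <- disc_point_stresses(w, disc, pts)
  expect_equal(s$sigma, 5000 * pts[, "y"] / Ix, tolerance = 1e-12)
  expect_equal(s$von_mises, abs(s$sigma), tolerance = 1e-12)
  # coronal bending honours the upper-on-lower wrench convention:
  # a stress field sigma = c x carries My = -c Iy
  cc <- 0.3
  Iy <- pi / 4 * r^4
  w2 <- list(N = 0, Mx = 0, My = -cc * Iy, T = 0)
  s2 <- disc_point_stresses(w2, disc, pts)
  expect_equal(s2$sigma, cc * pts[, "x"], tolerance = 1e-12)
  # pure torsion: tau = T r / J on the perimeter
  w3 <- list(N = 0, Mx = 0, My = 0, T = 2000)
  s3 <- disc_point_stresses(w3, disc, pts)
  expect_equal(s3$tau, rep(2000 * r / (Ix + Iy), 10), tolerance = 1e-12)
  expect_equal(s3$von_mises, sqrt(3) * s3$tau, tolerance = 1e-12)
})

test_that("sampled axial stresses average to N/A for any wrench", {
  dsc <- ref_geometry()$discs[[6]]
  A <- pi * dsc$a * dsc$b
  w <- list(N = -321, Mx = 1234, My = -567, T = 89)
  pc <- spinebrace:::side_sample_points(dsc$a, dsc$b, 1)
  pv <- spinebrace:::side_sample_points(dsc$a, dsc$b, -1)
  s <- disc_point_stresses(w, dsc, rbind(pc, pv))
  expect_equal(mean(s$sigma), w$N / A, tolerance = 1e-9)
})

test_that("upright scoliotic loading overloads the concave apex disc", {
  res <- study_result()
  up <- res$cases$upright
  mt_stress <- vapply(up$disc_stress[3:4], `[[`, 0, "stress_ratio")
  expect_true(all(mt_stress > 1))   # concave side carries more stress
  mt_height <- vapply(up$disc_height[3:4], `[[`, 0, "height_ratio")
  expect_true(all(mt_height < 1))   # concave space is narrower
})

test_that("muscle ratios are homogeneous of degree -1 in convex forces", {
  geo <- ref_geometry()
  mf <- upright_muscles()
  mr1 <- muscle_ratio(mf, geo)
  tab <- muscle_table(geo$muscles)
  mf2 <- mf
  convex_idx <- vapply(seq_along(geo$muscles), function(i) {
    side <- tab$side[i]
    cside <- spinebrace:::fascicle_concave_side(geo, geo$muscles[[i]])
    side != cside
  }, TRUE)
  mf2$force[convex_idx] <- 2 * mf2$force[convex_idx]
  mr2 <- muscle_ratio(mf2, geo)
  expect_equal(mr2$overall, mr1$overall / 2, tolerance = 1e-12)
  expect_equal(mr2$table$ratio, mr1$table$ratio / 2, tolerance = 1e-12)
})

test_that("ratios stay positive and finite across all solved cases", {
  res <- study_result()
  for (cs in names(res$cases)) {
    r <- res$cases[[cs]]
    hr <- vapply(r$disc_height, `[[`, 0, "height_ratio")
    sr <- vapply(r$disc_stress, `[[`, 0, "stress_ratio")
    expect_true(all(is.finite(hr) & hr > 0))
    expect_true(all(is.finite(sr) & sr > 0))
    expect_true(is.finite(r$muscle$overall) && r$muscle$overall > 0)
  }
})
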