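# helper: re-tilt one vertebra of a geometry in the coronal plane and
# rebuild its endplate landmarks
tilt_vertebra <- function(geometry, level, tilt_deg) {
  i <- match(level, vapply(geometry$vertebrae, `[[`, "", "level"))
  v <- geometry$vertebrae[[i]]
  R <- spinebrace:::rot_vec(c(0, spinebrace:::deg2rad(tilt_deg), 0)) %*% v$R
  corners <- rbind(c(1, 1), c(-1, 1), c(-1, -1), c(1, -1))
  v$R <- R
  v$sup <- t(apply(corners, 1, function(cc)
    v$centroid + R %*% c(cc[1] * v$width / 2, cc[2] * v$depth / 2, v$height / 2)))
  v$inf <- t(apply(corners, 1, function(cc)
    v$centroid + R %*% c(cc[1] * v$width / 2, cc[2] * v$depth / 2, -v$height / 2)))
  geometry$vertebrae[[i]] <- v
  geometry
}

test_that("Cobb angle reproduces planar geometry by hand", {
  geo <- straight_geometry()
  expect_equal(cobb_angle(geo, "T4", "T11"), 0, tolerance = 1e-10)
  g <- tilt_vertebra(tilt_vertebra(geo, "T4", 10), "T11", -10)
  expect_equal(cobb_angle(g, "T4", "T11"), 20, tolerance = 1e-9)
  expect_error(cobb_angle(geo, "T11", "T4"), "cranial")
})

test_that("sagittal angles recover the requested shape and decouple from coronal", {
  sag <- sagittal_angles(ref_geometry())
  expect_lt(abs(sag[["tk"]] - 10), 0.5)
  expect_lt(abs(sag[["ll"]] - 40.5), 0.5)
  # pure coronal curve leaves the sagittal plane untouched
  g <- generate_spine(curve_params(tk = 0, ll = 0))
  expect_equal(unname(sagittal_angles(g)), c(0, 0), tolerance = 1e-9)
  expect_lt(abs(radiographic_report(g)$mt_cobb - 38.5), 0.5)
})

test_that("AVT measures signed offset from the central sacral vertical line", {
  geo <- straight_geometry()
  expect_equal(avt(geo, "T7"), 0, tolerance = 1e-9)
  g <- geo
  i <- match("T7", vapply(g$vertebrae, `[[`, "", "level"))
  g$vertebrae[[i]]$centroid[1] <- g$vertebrae[[i]]$centroid[1] + 20
  expect_equal(avt(g, "T7"), 20, tolerance = 1e-9)
  expect_gt(avt(ref_geometry(), "T7"), 0)  # right-convex MT apex sits right
})

test_that("axial rotation round-trips and mirrors", {
  geo <- ref_geometry()
  expect_equal(axial_rotation(vertebra_by_level(geo, "T7")), 8, tolerance = 0.1)
  expect_equal(axial_rotation(vertebra_by_level(geo, "T2")), -3, tolerance = 0.1)
  g_neg <- generate_spine(curve_params(axial_rotation_t7 = -8))
  expect_equal(axial_rotation(vertebra_by_level(g_neg, "T7")), -8, tolerance = 0.1)
  expect_equal(axial_rotation(vertebra_by_level(straight_geometry(), "T7")), 0,
               tolerance = 1e-10)
})

test_that("correction rate follows the exact formula", {
  expect_equal(correction_rate(40, 40), 0)
  expect_equal(correction_rate(40, 20), 50)
  expect_equal(correction_rate(38.5, 18.85), 100 * (38.5 - 18.85) / 38.5)
  expect_error(correction_rate(0, 10), "positive")
})

test_that("rigid translation changes no angle", {
  geo <- ref_geometry()
  g <- geo
  shift <- c(12.3, -45.6, 78.9)
  for (i in seq_along(g$vertebrae)) {
    v <- g$vertebrae[[i]]
    v$centroid <- v$centroid + shift
    v$sup <- sweep(v$sup, 2, shift, "+")
    v$inf <- sweep(v$inf, 2, shift, "+")
    g$vertebrae[[i]] <- v
  }
  r0 <- radiographic_report(geo)
  r1 <- radiographic_report(g)
  for (fld in c("mt_cobb", "pt_cobb", "l_cobb", "tk", "ll"))
    expect_equal(r1[[fld]], r0[[fld]], tolerance = 1e-9)
})

test_that("the report records auto-selected end vertebrae", {
  rep_ <- radiographic_report(ref_geometry())
  expect_equal(unname(rep_$end_vertebrae$mt), c("T4", "T11"))
  expect_equal(unname(rep_$end_vertebrae$pt), c("T1", "T4"))
  expect_equal(unname(rep_$end_vertebrae$l), c("T11", "L4"))
  expect_false(rep_$flatback)  # TK = 10 sits at the diagnostic boundary
})
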