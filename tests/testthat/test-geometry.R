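test_that("reference parameters round-trip through generation and measurement", {
  geo <- ref_geometry()
  rep_ <- radiographic_report(geo)
  p <- geo$params
  expect_lt(abs(rep_$mt_cobb - p$mt_cobb), 0.5)
  expect_lt(abs(rep_$pt_cobb - p$pt_cobb), 0.5)
  expect_lt(abs(rep_$l_cobb - p$l_cobb), 0.5)
  expect_lt(abs(rep_$tk - p$tk), 0.5)
  expect_lt(abs(rep_$ll - p$ll), 0.5)
  expect_lt(abs(rep_$axial_rotation_t7 - p$axial_rotation_t7), 0.1)
  expect_lt(abs(rep_$axial_rotation_t2 - p$axial_rotation_t2), 0.1)
})

test_that("zero curve parameters give a straight vertical column", {
  geo <- straight_geometry()
  for (v in geo$vertebrae) {
    expect_equal(v$centroid[1], 0, tolerance = 1e-12)
    expect_equal(v$centroid[2], 0, tolerance = 1e-12)
    n <- spinebrace:::endplate_normal(v$sup)
    expect_equal(as.numeric(n), c(0, 0, 1), tolerance = 1e-12)
  }
  expect_equal(cobb_angle(geo, "T4", "T11"), 0, tolerance = 1e-10)
  expect_equal(unname(sagittal_angles(geo)), c(0, 0), tolerance = 1e-10)
})

test_that("structural invariants hold on the generated spine", {
  geo <- ref_geometry()
  expect_length(geo$vertebrae, 18)
  expect_length(geo$discs, length(geo$vertebrae) - 1)
  expect_length(geo$ligaments, 5 * (length(geo$vertebrae) - 1))
  for (v in geo$vertebrae) {
    expect_gt(v$height, 0)
    # superior endplate centroid above inferior along the local axis
    expect_gt(sum((colMeans(v$sup) - colMeans(v$inf)) * v$R[, 3]), 0)
  }
  for (d in geo$discs) expect_gt(d$height, 0)
  expect_identical(geo$concave_side[["mt"]], "left")
})

test_that("random valid draws round-trip within half a degree", {
  set.seed(421)
  for (k in 1:25) {
    p <- draw_params()
    geo <- generate_spine(p)
    rep_ <- radiographic_report(geo)
    expect_lt(abs(rep_$mt_cobb - p$mt_cobb), 0.5)
    expect_lt(abs(rep_$pt_cobb - p$pt_cobb), 0.5)
    expect_lt(abs(rep_$l_cobb - p$l_cobb), 0.5)
    expect_lt(abs(rep_$tk - p$tk), 0.5)
    expect_lt(abs(rep_$ll - p$ll), 0.5)
  }
})

test_that("generation is deterministic and scales linearly with stature", {
  g1 <- generate_spine(curve_params())
  g2 <- generate_spine(curve_params())
  expect_identical(g1, g2)
  tall <- generate_spine(curve_params(stature = 304))
  short <- ref_geometry()
  d_tall <- sapply(2:18, function(i)
    sqrt(sum((tall$vertebrae[[i]]$centroid - tall$vertebrae[[i - 1]]$centroid)^2)))
  d_short <- sapply(2:18, function(i)
    sqrt(sum((short$vertebrae[[i]]$centroid - short$vertebrae[[i - 1]]$centroid)^2)))
  expect_equal(d_tall, 2 * d_short, tolerance = 1e-12)
})

test_that("straight-spine fascicles mirror across the midline", {
  geo <- straight_geometry()
  tab <- muscle_table(geo$muscles)
  left <- geo$muscles[tab$side == "left"]
  right <- geo$muscles[tab$side == "right"]
  expect_equal(length(left), length(right))
  for (k in seq_along(left)) {
    expect_identical(left[[k]]$name, right[[k]]$name)
    expect_equal(left[[k]]$origin * c(-1, 1, 1), right[[k]]$origin, tolerance = 1e-12)
    expect_equal(left[[k]]$insertion * c(-1, 1, 1), right[[k]]$insertion,
                 tolerance = 1e-12)
  }
  # all 11 groups present bilaterally
  expect_setequal(unique(tab$name),
                  c("MF", "LGPT", "LGPL", "ICPT", "ICPL", "QL", "PM", "IP",
                    "RA", "EO", "IO"))
  expect_true(all(table(tab$name, tab$side) > 0))
})

test_that("convex-side extensors are longer at the thoracic apex", {
  geo <- ref_geometry()
  tab <- muscle_table(geo$muscles)
  apex <- match("T7", spine_levels())
  at_apex <- tab$name == "MF" & tab$origin_index %in% (apex - 1):(apex)
  len_r <- tab$length[at_apex & tab$side == "right"]  # convex side
  len_l <- tab$length[at_apex & tab$side == "left"]
  expect_true(all(len_r > len_l))
})

test_that("infeasible parameter sets are rejected", {
  expect_error(curve_params(mt_cobb = -5), "Cobb")
  expect_error(curve_params(apex_pt = "T7", apex_mt = "T2"), "ordered")
  expect_error(generate_spine(curve_params(mt_cobb = 40, pt_cobb = 1, l_cobb = 5)),
               "infeasible")
  expect_error(curve_params(body_mass = 0), "body_mass")
})

test_that("ligament stiffness rule and degenerate input behave as specified", {
  expect_equal(ligament_stiffness(31.5, 10, 10), 31.5)
  expect_error(ligament_stiffness(31.5, 10, 0), "positive")
  kinds <- table(vapply(ref_geometry()$ligaments, `[[`, "", "kind"))
  expect_equal(length(kinds), 5)
  expect_true(all(kinds == 17))
  for (lg in ref_geometry()$ligaments) {
    expect_gt(lg$stiffness, 0)
    expect_gt(lg$rest_length, 0)
  }
})
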