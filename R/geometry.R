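#' Vertebral level labels T1 to S1
#'
#' @return Character vector of the 18 modelled levels, cranial to caudal.
#' @export
spine_levels <- function() c(paste0("T", 1:12), paste0("L", 1:5), "S1")

level_index <- function(level) {
  i <- match(level, spine_levels())
  if (any(is.na(i))) stop("unknown vertebral level: ", paste(level[is.na(i)], collapse = ", "),
                          call. = FALSE)
  i
}

# Reference vertebral body dimensions (mm) at 152 cm stature, T1 -> S1.
# Approximate adolescent morphometric proportions; scaled linearly with
# stature by the generator.
ref_dims <- function() {
  list(
    height = c(14, 14.5, 15, 15.5, 16, 16.5, 17, 17.5, 18, 18.5, 19, 20,
               23, 24, 25, 26, 27, 30),
    width  = c(26, 27, 28, 29, 30, 31, 32, 33, 34, 36, 38, 40,
               42, 44, 46, 48, 50, 50),
    depth  = c(18, 19, 20, 21, 22, 22, 23, 24, 25, 26, 27, 28,
               30, 31, 32, 33, 34, 34),
    # disc nominal heights between consecutive levels (17 junctions)
    disc_h = c(4, 4, 4.2, 4.2, 4.4, 4.4, 4.6, 4.6, 4.8, 5, 5.2, 6,
               8, 9, 10, 10, 10)
  )
}

# Per-level trunk segment mass as a fraction of body mass, T1 -> L5.
# Approximates published trunk mass distributions (segment mass grows
# caudally); exposed so load_model can document and override it.
#' Default per-level trunk segment mass fractions
#'
#' Fraction of total body mass assigned to each vertebral level T1--L5,
#' increasing caudally, used by [vertebral_level_loads()].
#'
#' @return Named numeric vector (levels T1..L5).
#' @export
default_mass_fractions <- function() {
  f <- c(0.010, 0.011, 0.012, 0.013, 0.014, 0.015, 0.016, 0.017, 0.018,
         0.019, 0.020, 0.021, 0.023, 0.025, 0.027, 0.029, 0.031)
  names(f) <- spine_levels()[1:17]
  f
}

#' Scoliotic curve parameters
#'
#' Parametric description of a double thoracic + lumbar (Rigo A3-like)
#' scoliotic spine: coronal Cobb angles of the proximal thoracic (PT), main
#' thoracic (MT) and lumbar (L) curves, sagittal thoracic kyphosis (TK) and
#' lumbar lordosis (LL), apical axial rotations, and patient anthropometry.
#' The default values are the pre-brace radiological measurements of the
#' reference patient (13 y, 152 cm, 42 kg).
#'
#' Convexity pattern: MT convex right (concave left), PT and L convex left
#' (concave right).
#'
#' @param mt_cobb,pt_cobb,l_cobb Coronal Cobb angles, degrees, in [0, 90).
#' @param tk,ll Thoracic kyphosis (T1--T12) and lumbar lordosis (L1--S1),
#'   degrees.
#' @param apex_mt,apex_pt,apex_l Apex vertebral levels of the three curves.
#' @param axial_rotation_t2,axial_rotation_t7 Apical axial rotations, degrees
#'   (positive = towards patient right).
#' @param body_mass Patient mass, kg.
#' @param stature Patient height, cm. All linear dimensions scale with it.
#' @param seed Integer recorded in the geometry provenance; generation itself
#'   is fully deterministic.
#' @return A `curve_params` object.
#' @export
curve_params <- function(mt_cobb = 38.5, pt_cobb = 19.8, l_cobb = 34,
                         tk = 10, ll = 40.5,
                         apex_mt = "T7", apex_pt = "T2", apex_l = "L2",
                         axial_rotation_t2 = -3, axial_rotation_t7 = 8,
                         body_mass = 42, stature = 152, seed = 1L) {
  p <- list(mt_cobb = mt_cobb, pt_cobb = pt_cobb, l_cobb = l_cobb,
            tk = tk, ll = ll,
            apex_mt = apex_mt, apex_pt = apex_pt, apex_l = apex_l,
            axial_rotation_t2 = axial_rotation_t2,
            axial_rotation_t7 = axial_rotation_t7,
            body_mass = body_mass, stature = stature, seed = as.integer(seed))
  class(p) <- "curve_params"
  validate_curve_params(p)
  p
}

validate_curve_params <- function(p) {
  ang <- c(p$mt_cobb, p$pt_cobb, p$l_cobb)
  if (any(ang < 0) || any(ang >= 90)) {
    stop("Cobb angles must lie in [0, 90)", call. = FALSE)
  }
  if (p$body_mass <= 0) stop("body_mass must be positive", call. = FALSE)
  if (p$stature <= 0) stop("stature must be positive", call. = FALSE)
  ia <- level_index(c(p$apex_pt, p$apex_mt, p$apex_l))
  if (any(diff(ia) <= 0)) {
    stop("apex levels must be strictly ordered cranial to caudal", call. = FALSE)
  }
  invisible(p)
}

# Coronal endplate-tilt knots for the three-curve pattern. Tilt is the
# coronal-plane inclination of the endplate (positive = superior surface
# tips towards +X). Apices carry zero tilt (lateral-offset extremum); curve
# end vertebrae carry the extreme tilts, so the endplate Cobb between the
# auto-selected end vertebrae equals the requested angle by construction.
coronal_tilt_knots <- function(p) {
  i_pt <- level_index(p$apex_pt); i_mt <- level_index(p$apex_mt)
  i_l <- level_index(p$apex_l)
  # fixed default curve bounds, recorded in every report
  e_pt_up <- 1                       # T1
  e_pt_mt <- level_index("T4")       # shared PT/MT end
  e_mt_l  <- level_index("T11")      # shared MT/L end
  e_l_lo  <- level_index("L4")
  mt <- p$mt_cobb; pt <- p$pt_cobb; l <- p$l_cobb
  if (mt == 0 && pt == 0 && l == 0) {
    return(list(idx = c(1, 18), val = c(0, 0),
                bounds = list(pt = c(e_pt_up, e_pt_mt), mt = c(e_pt_mt, e_mt_l),
                              l = c(e_mt_l, e_l_lo))))
  }
  if (mt <= 0) stop("unsupported curve pattern: mt_cobb must be > 0 unless all Cobb angles are 0",
                    call. = FALSE)
  # split of the MT Cobb between its two end tilts, chosen so the adjacent
  # curves keep alternating (measurable) end tilts
  r_lo <- 1 - 0.85 * l / mt
  r_hi <- 0.85 * pt / mt
  r <- min(max(0.35, r_lo), r_hi)
  if (r_lo > r_hi || r <= 0 || r >= 1) {
    stop("infeasible curve parameter set: PT/MT/L Cobb combination has no alternating tilt pattern",
         call. = FALSE)
  }
  a1 <- -mt * r          # tilt at shared PT/MT end (T4)
  a2 <- mt * (1 - r)     # tilt at shared MT/L end (T11)
  a0 <- a1 + pt          # tilt at T1
  a3 <- a2 - l           # tilt at L4
  list(idx = c(e_pt_up, i_pt, e_pt_mt, i_mt, e_mt_l, i_l, e_l_lo, 18),
       val = deg2rad(c(a0, 0, a1, 0, a2, 0, a3, 0)),
       bounds = list(pt = c(e_pt_up, e_pt_mt), mt = c(e_pt_mt, e_mt_l),
                     l = c(e_mt_l, e_l_lo)))
}

sagittal_tilt_knots <- function(p) {
  i_t8 <- level_index("T8")
  list(idx = c(1, i_t8, level_index("T12"), level_index("L1"), 18),
       val = deg2rad(c(p$tk / 2, 0, -p$tk / 2, -p$tk / 2, -p$tk / 2 + p$ll)))
}

axial_rotation_knots <- function(p) {
  list(idx = c(1, level_index(p$apex_pt), level_index("T4"),
               level_index(p$apex_mt), level_index("T11"), 18),
       val = deg2rad(c(0, p$axial_rotation_t2, 0, p$axial_rotation_t7, 0, 0)))
}

#' Generate a parametric scoliotic spine geometry
#'
#' Builds an ordered rigid-vertebra chain T1--S1: vertebral centroids follow
#' piecewise-cosine coronal and sagittal arcs through the requested apices,
#' endplate orientations are set so that endplate-based Cobb, TK and LL
#' measurements recover the requested angles exactly, and apical axial
#' rotation is interpolated to zero at the curve end vertebrae. Vertebral
#' body dimensions follow adolescent morphometric proportions scaled
#' linearly with stature. Discs, tension-only ligaments and the bilateral
#' trunk muscle fascicle set are attached.
#'
#' @param params A [curve_params()] object.
#' @param materials A material table; defaults to [default_materials()].
#' @return A `spine_geometry` object: lists `vertebrae`, `discs`,
#'   `ligaments`, `muscles`, plus `concave_side`, `curve_bounds`, `params`.
#' @examples
#' geo <- generate_spine(curve_params())
#' length(geo$vertebrae)  # 18 levels T1..S1
#' @export
generate_spine <- function(params, materials = default_materials()) {
  validate_curve_params(params)
  validate_materials(materials)
  dims <- ref_dims()
  s <- params$stature / 152
  h <- dims$height * s; w <- dims$width * s; d <- dims$depth * s
  dh <- dims$disc_h * s
  n <- 18
  idx <- seq_len(n)

  ck <- coronal_tilt_knots(params)
  theta <- smoothstep_interp(ck$idx, ck$val, idx)       # coronal tilt, rad
  sk <- sagittal_tilt_knots(params)
  phi <- smoothstep_interp(sk$idx, sk$val, idx)         # sagittal tilt, rad
  ak <- axial_rotation_knots(params)
  rho <- linear_interp(ak$idx, ak$val, idx)             # axial rotation, rad

  # centroid path, integrated bottom-up from S1 at the origin
  cen <- matrix(0, n, 3)
  for (i in (n - 1):1) {
    th_m <- (theta[i] + theta[i + 1]) / 2
    ph_m <- (phi[i] + phi[i + 1]) / 2
    u <- unit3(c(tan(th_m), tan(ph_m), 1))
    len <- h[i + 1] / 2 + dh[i] + h[i] / 2
    cen[i, ] <- cen[i + 1, ] + len * u
  }

  vertebrae <- vector("list", n)
  for (i in idx) {
    t_i <- unit3(c(tan(theta[i]), tan(phi[i]), 1))
    R <- rot_align_z(t_i) %*% rot_z(rho[i])
    corners <- rbind(c(1, 1), c(-1, 1), c(-1, -1), c(1, -1))
    sup <- t(apply(corners, 1, function(cc)
      cen[i, ] + R %*% c(cc[1] * w[i] / 2, cc[2] * d[i] / 2, h[i] / 2)))
    inf <- t(apply(corners, 1, function(cc)
      cen[i, ] + R %*% c(cc[1] * w[i] / 2, cc[2] * d[i] / 2, -h[i] / 2)))
    vertebrae[[i]] <- list(
      level = spine_levels()[i], centroid = cen[i, ], R = R,
      width = w[i], depth = d[i], height = h[i],
      sup = sup, inf = inf,
      coronal_tilt = rad2deg(theta[i]), sagittal_tilt = rad2deg(phi[i]),
      axial_rotation = rad2deg(rho[i])
    )
  }

  discs <- vector("list", n - 1)
  for (i in seq_len(n - 1)) {
    up <- vertebrae[[i]]; lo <- vertebrae[[i + 1]]
    c_up <- colMeans(up$inf); c_lo <- colMeans(lo$sup)
    center <- (c_up + c_lo) / 2
    axis <- unit3(c_up - c_lo)
    xd <- (up$R[, 1] + lo$R[, 1]) / 2
    xd <- unit3(xd - sum(xd * axis) * axis)
    yd <- c(axis[2] * xd[3] - axis[3] * xd[2],
            axis[3] * xd[1] - axis[1] * xd[3],
            axis[1] * xd[2] - axis[2] * xd[1])
    Rd <- cbind(xd, yd, axis)  # local x lateral, y anterior, z axial
    a_lat <- 0.45 * (up$width + lo$width) / 2    # annulus outer semi-axes
    b_ap <- 0.45 * (up$depth + lo$depth) / 2
    discs[[i]] <- list(
      upper_level = up$level, lower_level = lo$level,
      center = center, R = Rd, height = dh[i],
      a = a_lat, b = b_ap, nucleus_fraction = 0.4,
      annulus = "annulus fibrosus", nucleus = "nucleus pulposus"
    )
  }

  geo <- list(
    vertebrae = vertebrae, discs = discs,
    concave_side = c(pt = "right", mt = "left", l = "right"),
    curve_bounds = lapply(ck$bounds, function(b) spine_levels()[b]),
    apices = c(pt = params$apex_pt, mt = params$apex_mt, l = params$apex_l),
    params = params, materials = materials
  )
  class(geo) <- "spine_geometry"
  geo$ligaments <- default_ligaments(geo, materials)
  geo$muscles <- default_muscles(geo)
  geo
}

#' @export
print.spine_geometry <- function(x, ...) {
  p <- x$params
  cat("spine_geometry: T1-S1,", length(x$vertebrae), "vertebrae,",
      length(x$discs), "discs,", length(x$ligaments), "ligament segments,",
      length(x$muscles), "muscle fascicles\n")
  cat(sprintf("  requested: MT %.1f / PT %.1f / L %.1f deg, TK %.1f, LL %.1f; %g kg, %g cm\n",
              p$mt_cobb, p$pt_cobb, p$l_cobb, p$tk, p$ll, p$body_mass, p$stature))
  invisible(x)
}

vertebra_by_level <- function(geometry, level) {
  i <- match(level, vapply(geometry$vertebrae, `[[`, "", "level"))
  if (is.na(i)) stop("level ", level, " not present in geometry", call. = FALSE)
  geometry$vertebrae[[i]]
}

disc_by_levels <- function(geometry, upper_level) {
  i <- match(upper_level, vapply(geometry$discs, `[[`, "", "upper_level"))
  if (is.na(i)) stop("no disc below ", upper_level, call. = FALSE)
  geometry$discs[[i]]
}
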