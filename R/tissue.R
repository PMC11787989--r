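# Disc and muscle outcome metrics computed from an equilibrium state:
# concave/convex intervertebral-space height ratios, concave/convex von
# Mises stress ratios from 10-point perimeter sampling, and muscle
# axial-force balance ratios.

# Region (pt / mt / l) owning a disc, from the geometry's curve bounds.
disc_region <- function(geometry, upper_level) {
  i <- level_index(upper_level)
  b <- lapply(geometry$curve_bounds, level_index)
  if (i < b$pt[2]) "pt" else if (i < b$mt[2]) "mt" else "l"
}

concave_x_sign <- function(geometry, region) {
  if (geometry$concave_side[[region]] == "right") 1 else -1
}

# Intersection of the line through `base` along `axis` with the plane of an
# endplate (through its centroid, normal from its landmarks).
plate_intersection <- function(landmarks, base, axis) {
  n <- endplate_normal(landmarks)
  c0 <- colMeans(landmarks)
  denom <- sum(axis * n)
  if (abs(denom) < 1e-9) stop("disc axis parallel to endplate", call. = FALSE)
  base + (sum((c0 - base) * n) / denom) * axis
}

#' Concave/convex intervertebral space height ratio of a disc
#'
#' Heights are measured in the deformed state between the inferior endplate
#' of the upper vertebra and the superior endplate of the lower vertebra,
#' at the lateral annulus margins on the concave and convex sides, along
#' the disc axis. The concave side is inherited from the curve region
#' containing the disc.
#'
#' @param state An `equilibrium_state`.
#' @param upper_level Upper vertebra label identifying the disc.
#' @return A list: `disc`, `region`, `height_concave`, `height_convex`
#'   (mm), `height_ratio` (concave/convex), `penetration` flag.
#' @export
disc_height_ratio <- function(state, upper_level) {
  g <- state$deformed
  e <- level_index(upper_level)
  dsc <- g$discs[[e]]
  up <- g$vertebrae[[e]]; lo <- g$vertebrae[[e + 1]]
  region <- disc_region(g, upper_level)
  s_conc <- concave_x_sign(g, region)
  height_at <- function(s) {
    base <- dsc$center + s * dsc$a * dsc$R[, 1]
    qu <- plate_intersection(up$inf, base, dsc$R[, 3])
    ql <- plate_intersection(lo$sup, base, dsc$R[, 3])
    sum((qu - ql) * dsc$R[, 3])
  }
  hc <- height_at(s_conc)
  hv <- height_at(-s_conc)
  list(disc = paste(dsc$upper_level, dsc$lower_level, sep = "-"),
       region = region, height_concave = hc, height_convex = hv,
       height_ratio = hc / hv, penetration = (hc <= 0 || hv <= 0))
}

# Perimeter sampling points: `npts` points on a `arc_deg` lateral arc of
# the annulus ellipse, centred on the given side of the local x axis.
side_sample_points <- function(a, b, side_sign, npts = 10, arc_deg = 120) {
  centre <- if (side_sign >= 0) 0 else pi
  psi <- centre + deg2rad(seq(-arc_deg / 2, arc_deg / 2, length.out = npts))
  cbind(x = a * cos(psi), y = b * sin(psi))
}

#' Composite-section stresses at perimeter points of a disc
#'
#' Normal stress `sigma = N/A + Mx y / Ix + My x / Iy` and torsional shear
#' `tau = T r / J` from the disc wrench, combined as von Mises
#' `sqrt(sigma^2 + 3 tau^2)`.
#'
#' @param wrench Disc wrench (local frame) from an `equilibrium_state`.
#' @param disc Disc record (section geometry).
#' @param points Matrix of local (x, y) sampling points, mm.
#' @return Data frame with `x`, `y`, `sigma`, `tau`, `von_mises` (MPa).
#' @export
disc_point_stresses <- function(wrench, disc, points) {
  A <- pi * disc$a * disc$b
  Ix <- pi / 4 * disc$a * disc$b^3
  Iy <- pi / 4 * disc$b * disc$a^3
  J <- Ix + Iy
  if (A <= 0) stop("zero disc cross-section", call. = FALSE)
  x <- points[, 1]; y <- points[, 2]
  # wrench components are the action of the upper body on the lower, on the
  # section face with outward normal +z: Mx = int(sigma y dA),
  # My = -int(sigma x dA), hence the sign of the My term
  sigma <- wrench$N / A + wrench$Mx * y / Ix - wrench$My * x / Iy
  tau <- wrench$T * sqrt(x^2 + y^2) / J
  data.frame(x = x, y = y, sigma = sigma, tau = tau,
             von_mises = sqrt(sigma^2 + 3 * tau^2))
}

#' Concave/convex von Mises stress ratio of a disc
#'
#' Samples `npts` equally spaced points on a lateral arc of the annulus
#' perimeter on each side, evaluates the composite-section von Mises
#' stress from the internal disc wrench at each, and forms the ratio of
#' side means (concave / convex).
#'
#' @inheritParams disc_height_ratio
#' @param npts Points per side (default 10).
#' @param arc_deg Lateral arc spanned by the samples, degrees.
#' @return A list: `disc`, `region`, per-side mean stresses (MPa), the 10
#'   sampled values per side, and `stress_ratio`.
#' @export
disc_stress_ratio <- function(state, upper_level, npts = 10, arc_deg = 120) {
  g <- state$deformed
  e <- level_index(upper_level)
  dsc <- state$model$geometry$discs[[e]]  # section geometry (reference)
  w <- state$wrench[[e]]
  region <- disc_region(g, upper_level)
  s_conc <- concave_x_sign(g, region)
  pc <- side_sample_points(dsc$a, dsc$b, s_conc, npts, arc_deg)
  pv <- side_sample_points(dsc$a, dsc$b, -s_conc, npts, arc_deg)
  sc <- disc_point_stresses(w, dsc, pc)
  sv <- disc_point_stresses(w, dsc, pv)
  list(disc = paste(dsc$upper_level, dsc$lower_level, sep = "-"),
       region = region,
       mean_concave = mean(sc$von_mises), mean_convex = mean(sv$von_mises),
       concave_points = sc$von_mises, convex_points = sv$von_mises,
       stress_ratio = mean(sc$von_mises) / mean(sv$von_mises))
}

paravertebral_groups <- function() c("MF", "LGPT", "LGPL", "ICPT", "ICPL", "QL", "PM")

# Concave side (left/right) seen by a fascicle: thoracic fascicles take the
# main-thoracic concavity, lumbar fascicles the lumbar concavity.
fascicle_concave_side <- function(geometry, fascicle) {
  if (fascicle$origin_index <= level_index("T11")) {
    geometry$concave_side[["mt"]]
  } else {
    geometry$concave_side[["l"]]
  }
}

#' Concave/convex muscle axial-force ratios
#'
#' Per-group sums of fascicle tensions on the concave and convex sides
#' (thoracic groups use the main-thoracic concavity, lumbar groups the
#' lumbar concavity) and their ratios, plus the overall paravertebral
#' ratio over MF, LG, IC, QL and PM.
#'
#' @param muscle_forces A `muscle_forces` object.
#' @param geometry The geometry the forces were optimized on.
#' @return A `muscle_ratio` list: per-group data frame (`group`,
#'   `concave`, `convex`, `ratio`) and `overall` paravertebral ratio.
#' @export
muscle_ratio <- function(muscle_forces, geometry) {
  fas <- muscle_forces$fascicles
  f <- muscle_forces$force
  groups <- unique(vapply(fas, `[[`, "", "name"))
  rows <- lapply(groups, function(gp) {
    idx <- which(vapply(fas, `[[`, "", "name") == gp)
    conc <- 0; conv <- 0
    for (i in idx) {
      side <- fas[[i]]$side
      cside <- fascicle_concave_side(geometry, fas[[i]])
      if (side == cside) conc <- conc + f[i] else conv <- conv + f[i]
    }
    data.frame(group = gp, concave = conc, convex = conv,
               ratio = if (conv > 0) conc / conv else NA_real_,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  par_ <- tab[tab$group %in% paravertebral_groups(), ]
  if (sum(par_$convex) <= 0) stop("zero convex-side paravertebral force", call. = FALSE)
  structure(list(table = tab, overall = sum(par_$concave) / sum(par_$convex)),
            class = "muscle_ratio")
}

#' @export
print.muscle_ratio <- function(x, ...) {
  print(transform(x$table, ratio = round(ratio, 3)), row.names = FALSE)
  cat(sprintf("overall paravertebral concave/convex ratio: %.3f\n", x$overall))
  invisible(x)
}
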