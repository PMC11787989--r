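# Load model: per-level gravity forces and Cheneau-style brace pressure
# patches (upright and CFEM1-4 combinations).

GRAVITY <- 9.81  # m/s^2

#' Per-level gravity loads
#'
#' Cumulative supported mass at vertebral level i follows
#' `Ptot_i = 15 + 2.1 * Mass_i` (kg), where `Mass_i` is the trunk segment
#' mass assigned to level i; the per-level increment is
#' `dPtot_i = Ptot_i - Ptot_{i-1}` (the full `Ptot_1` at the first level)
#' and the applied force is `dForce_i = dPtot_i * g` N, acting along -Z at
#' each vertebral centroid. The constant 15 and slope 2.1 are exposed as
#' arguments.
#'
#' @param body_mass Patient mass, kg.
#' @param level_mass Named vector of per-level segment masses (kg),
#'   cranial to caudal. Default: [default_mass_fractions()] * `body_mass`.
#' @param offset,slope Constants of the cumulative-mass relation (kg, -).
#' @param g Gravitational acceleration, m/s^2.
#' @return A `gravity_load`: data frame with `level`, `mass` (kg), `ptot`
#'   (kg), `dptot` (kg), `force` (N, magnitude of the -Z force).
#' @examples
#' gl <- vertebral_level_loads(42)
#' sum(gl$force) - GRAVITY * gl$ptot[nrow(gl)]  # conservation: ~0
#' @export
vertebral_level_loads <- function(body_mass,
                                  level_mass = default_mass_fractions() * body_mass,
                                  offset = 15, slope = 2.1, g = GRAVITY) {
  if (any(level_mass < 0) || body_mass <= 0) {
    stop("masses must be non-negative and body_mass positive", call. = FALSE)
  }
  if (sum(level_mass) > body_mass) {
    stop("modelled trunk segment masses exceed total body mass", call. = FALSE)
  }
  ptot <- offset + slope * level_mass
  if (any(diff(ptot) < 0)) {
    stop("cumulative mass must increase cranial to caudal", call. = FALSE)
  }
  dptot <- c(ptot[1], diff(ptot))
  out <- data.frame(
    level = if (is.null(names(level_mass))) spine_levels()[seq_along(level_mass)]
            else names(level_mass),
    mass = as.numeric(level_mass),
    ptot = as.numeric(ptot),
    dptot = as.numeric(dptot),
    force = as.numeric(dptot * g),
    stringsAsFactors = FALSE
  )
  class(out) <- c("gravity_load", "data.frame")
  out
}

# Regional pressure-tolerance thresholds (MPa)
trunk_threshold <- function() 0.035
axilla_threshold <- function() 0.085

# Patch catalogue: areas (cm^2) and verbal direction semantics made
# concrete in the global frame. "dorsolateral to ventromedial" pushes from
# the patch side towards the midline and anteriorly at 45 deg;
# "ventrolateral to dorsomedial" mirrors the Y sign; "vertical up" is +Z.
# Target mapping: the axillary patches act on the upper thoracic levels,
# the thoracic pad on the main-thoracic apex region T5-T8, and the waist
# pad transmits through the 11th/12th ribs and flank to the thoracolumbar
# junction T11-L1.
patch_catalogue <- function() {
  data.frame(
    region = c("left axillary", "left lumbar", "right thorax",
               "left axillary inferior", "right axillary inferior"),
    area = c(38.5, 116.0, 143.9, 47.1, 23.5),     # cm^2
    direction = c("ventrolateral to dorsomedial",
                  "dorsolateral to ventromedial",
                  "dorsolateral to ventromedial",
                  "vertical up", "vertical up"),
    side = c("left", "left", "right", "left", "right"),
    threshold = c(0.085, 0.035, 0.035, 0.085, 0.085),
    targets = I(list(c("T3", "T4", "T5"), c("T11", "T12", "L1"),
                     c("T5", "T6", "T7", "T8"), c("T1", "T2"), c("T1", "T2"))),
    stringsAsFactors = FALSE
  )
}

patch_direction_vector <- function(direction, side) {
  sg <- if (side == "left") -1 else 1   # patch sits on this side of the torso
  switch(direction,
    "dorsolateral to ventromedial" = unit3(c(-sg, 1, 0)),
    "ventrolateral to dorsomedial" = unit3(c(-sg, -1, 0)),
    "vertical up" = c(0, 0, 1),
    stop("unknown patch direction: ", direction, call. = FALSE)
  )
}

#' Construct a brace pressure patch
#'
#' Resultant force magnitude is `pressure * area` (MPa x cm^2 -> N via
#' 1 MPa * 1 cm^2 = 100 N). Construction fails if the pressure exceeds the
#' regional pain-tolerance threshold (0.035 MPa trunk, 0.085 MPa axilla).
#'
#' @param region One of the five catalogue regions.
#' @param pressure Applied pressure, MPa.
#' @param geometry A `spine_geometry` (for lever-arm offsets).
#' @param targets Optional override of the target vertebral levels the
#'   patch resultant maps to.
#' @return A `pressure_patch`: region, area (cm^2), pressure (MPa), unit
#'   `direction`, resultant `force` (N), target vertebral `targets`, and
#'   per-target application points (mm).
#' @export
pressure_patch <- function(region, pressure, geometry, targets = NULL) {
  cat_ <- patch_catalogue()
  i <- match(region, cat_$region)
  if (is.na(i)) stop("unknown patch region: ", region, call. = FALSE)
  if (pressure < 0) stop("pressure must be non-negative", call. = FALSE)
  if (pressure > cat_$threshold[i] + 1e-12) {
    stop(sprintf("pressure %.4g MPa exceeds the %s tolerance threshold %.3g MPa",
                 pressure, region, cat_$threshold[i]), call. = FALSE)
  }
  dir <- patch_direction_vector(cat_$direction[i], cat_$side[i])
  if (is.null(targets)) targets <- cat_$targets[[i]]
  s <- geometry$params$stature / 152
  el <- torso_ellipse(s)
  sg <- if (cat_$side[i] == "left") -1 else 1
  pts <- lapply(targets, function(lv) {
    v <- vertebra_by_level(geometry, lv)
    # application point on the torso surface: lateral offset of half the
    # torso ellipse width on the patch side, and half the depth opposite
    # to the anterior/posterior push component
    v$centroid + c(sg * el[["a"]], -sign(dir[2]) * el[["b"]], 0)
  })
  structure(list(
    region = region, area = cat_$area[i], pressure = pressure,
    direction = dir, force = pressure * cat_$area[i] * 100,  # N
    targets = targets, points = pts, side = cat_$side[i]
  ), class = "pressure_patch")
}

#' Build a brace load case (CFEM combination or upright)
#'
#' `"upright"` carries gravity only. CFEM1--4 add the five Cheneau patches:
#' left axillary, right thorax at the 0.035 MPa trunk threshold, both
#' axillary-inferior vertical-up patches at the 0.085 MPa axillary
#' threshold (resultants ~400 N left / ~200 N right), and a left-lumbar
#' pressure of 0.009, 0.018, 0.026, 0.035 MPa for CFEM1..CFEM4.
#'
#' @param combo `"upright"` or `"CFEM1"`..`"CFEM4"`.
#' @param geometry A `spine_geometry`.
#' @param lumbar_pressure Optional explicit left-lumbar pressure (MPa),
#'   overriding the combination value.
#' @param patch_targets Optional named list (`region` -> level vector)
#'   overriding the patch-to-vertebra mapping.
#' @return A `load_case`: label, [vertebral_level_loads()] gravity table,
#'   list of patches, and the boundary-condition set (sacrum fixed; T1
#'   free in lateral/forward bending and vertical translation).
#' @export
brace_load_case <- function(combo, geometry, lumbar_pressure = NULL,
                            patch_targets = list()) {
  lumbar <- c(CFEM1 = 0.009, CFEM2 = 0.018, CFEM3 = 0.026, CFEM4 = 0.035)
  gl <- vertebral_level_loads(geometry$params$body_mass)
  if (identical(combo, "upright")) {
    patches <- list()
  } else {
    if (!combo %in% names(lumbar)) stop("unknown load combination: ", combo, call. = FALSE)
    p_l <- if (is.null(lumbar_pressure)) lumbar[[combo]] else lumbar_pressure
    tg <- function(region) patch_targets[[region]]  # NULL -> catalogue default
    patches <- list(
      pressure_patch("left axillary", trunk_threshold(), geometry,
                     tg("left axillary")),
      pressure_patch("left lumbar", p_l, geometry, tg("left lumbar")),
      pressure_patch("right thorax", trunk_threshold(), geometry,
                     tg("right thorax")),
      pressure_patch("left axillary inferior", axilla_threshold(), geometry,
                     tg("left axillary inferior")),
      pressure_patch("right axillary inferior", axilla_threshold(), geometry,
                     tg("right axillary inferior"))
    )
  }
  structure(list(
    label = combo, gravity = gl, patches = patches,
    boundary = list(fixed = "S1",
                    t1_free = c("rot_x", "rot_y", "trans_z"))
  ), class = "load_case")
}

#' Series of load cases over a lumbar-pressure sweep
#'
#' One load case per fraction of the maximum left-lumbar corrective
#' pressure; all other patches stay at their thresholds. Pressures are
#' rounded to 3 decimals (MPa), matching the tabulated CFEM pressures.
#'
#' @param geometry A `spine_geometry`.
#' @param max_lumbar_pressure Maximum lumbar pressure, MPa.
#' @param fractions Fractions in (0, 1].
#' @return List of `load_case` objects labelled `CPLL<percent>`.
#' @export
cfem_series <- function(geometry, max_lumbar_pressure = trunk_threshold(),
                        fractions = c(0.25, 0.50, 0.75, 1.00)) {
  if (length(fractions) == 0) stop("empty fraction list", call. = FALSE)
  if (any(fractions <= 0 | fractions > 1)) {
    stop("fractions must lie in (0, 1]", call. = FALSE)
  }
  lapply(fractions, function(f) {
    lc <- brace_load_case("CFEM4", geometry,
                          lumbar_pressure = round(f * max_lumbar_pressure, 3))
    lc$label <- sprintf("CPLL%d", round(100 * f))
    lc
  })
}
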