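# Radiographic measurement on (possibly deformed) geometries: endplate-based
# Cobb angles in the coronal projection, sagittal TK/LL, apical vertebral
# translation against the central sacral vertical line, axial rotation, and
# the Cobb correction rate.

endplate_normal <- function(landmarks) {
  v1 <- landmarks[2, ] - landmarks[1, ]
  v2 <- landmarks[4, ] - landmarks[1, ]
  n <- crossprod3(v1, v2)
  nn <- sqrt(sum(n^2))
  if (nn < 1e-9) stop("degenerate endplate: landmarks are collinear", call. = FALSE)
  n <- n / nn
  if (n[3] < 0) n <- -n
  n
}

# Inclination (degrees) of the endplate line in the coronal (X-Z) or
# sagittal (Y-Z) projection, from the endplate plane normal.
endplate_tilt <- function(landmarks, plane = c("coronal", "sagittal")) {
  plane <- match.arg(plane)
  n <- endplate_normal(landmarks)
  if (abs(n[3]) < 1e-9) stop("degenerate endplate projection: plate is vertical",
                             call. = FALSE)
  if (plane == "coronal") rad2deg(atan2(n[1], n[3])) else rad2deg(atan2(n[2], n[3]))
}

#' Cobb angle between two end vertebrae
#'
#' Angle between the superior endplate of the upper end vertebra and the
#' inferior endplate of the lower end vertebra, both taken in the coronal
#' (X-Z) projection; always non-negative.
#'
#' @param geometry A `spine_geometry`.
#' @param upper_end,lower_end Level labels, `upper_end` cranial.
#' @return Cobb angle, degrees.
#' @examples
#' geo <- generate_spine(curve_params())
#' cobb_angle(geo, "T4", "T11")  # ~ the requested MT Cobb
#' @export
cobb_angle <- function(geometry, upper_end, lower_end) {
  if (level_index(upper_end) >= level_index(lower_end)) {
    stop("upper_end must be cranial to lower_end", call. = FALSE)
  }
  tu <- endplate_tilt(vertebra_by_level(geometry, upper_end)$sup, "coronal")
  tl <- endplate_tilt(vertebra_by_level(geometry, lower_end)$inf, "coronal")
  abs(tu - tl)
}

# Auto-selection of end vertebrae: the maximally tilted vertebrae (coronal
# projection) on each side of the apex, searched between neighbouring
# apices (standard Cobb convention). `convex` is "left" or "right".
select_end_vertebrae <- function(geometry, apex, search_upper, search_lower,
                                 convex) {
  s <- if (convex == "right") 1 else -1
  tilt <- vapply(geometry$vertebrae, function(v)
    endplate_tilt(v$sup, "coronal"), 0)
  iu <- search_upper[which.min(s * tilt[search_upper])]
  il <- search_lower[which.max(s * tilt[search_lower])]
  c(upper = iu, lower = il)
}

#' Sagittal thoracic kyphosis and lumbar lordosis
#'
#' TK between the superior endplate of `tk_range[1]` and the inferior
#' endplate of `tk_range[2]`; LL between the superior endplates of
#' `ll_range[1]` and `ll_range[2]`; magnitudes, degrees, measured in the
#' sagittal (Y-Z) projection.
#'
#' @param geometry A `spine_geometry`.
#' @param tk_range,ll_range Level ranges used (defaults T1--T12, L1--S1).
#' @return Named numeric vector `c(tk =, ll =)`.
#' @export
sagittal_angles <- function(geometry, tk_range = c("T1", "T12"),
                            ll_range = c("L1", "S1")) {
  tkv <- abs(endplate_tilt(vertebra_by_level(geometry, tk_range[1])$sup, "sagittal") -
             endplate_tilt(vertebra_by_level(geometry, tk_range[2])$inf, "sagittal"))
  llv <- abs(endplate_tilt(vertebra_by_level(geometry, ll_range[1])$sup, "sagittal") -
             endplate_tilt(vertebra_by_level(geometry, ll_range[2])$sup, "sagittal"))
  c(tk = tkv, ll = llv)
}

#' Apical vertebral translation (AVT)
#'
#' Signed horizontal (X) distance of the apical vertebral centroid from
#' the central sacral vertical line (the vertical through the S1 superior
#' endplate midpoint in the coronal projection); positive to the patient
#' right.
#'
#' @param geometry A `spine_geometry` containing S1.
#' @param apex_level Apical vertebra label.
#' @return AVT, mm.
#' @export
avt <- function(geometry, apex_level) {
  lev <- vapply(geometry$vertebrae, `[[`, "", "level")
  if (!"S1" %in% lev) stop("S1 is required to define the CSVL", call. = FALSE)
  s1 <- vertebra_by_level(geometry, "S1")
  csvl_x <- mean(s1$sup[, 1])
  vertebra_by_level(geometry, apex_level)$centroid[1] - csvl_x
}

#' Axial rotation of a vertebra
#'
#' Rotation of the local left-right axis about the global vertical,
#' degrees; zero when the vertebra faces straight ahead, positive towards
#' the patient right shoulder moving back (right axial rotation).
#'
#' @param vertebra A vertebra record from a `spine_geometry`.
#' @return Degrees.
#' @export
axial_rotation <- function(vertebra) {
  ex <- vertebra$R %*% c(1, 0, 0)
  rad2deg(atan2(ex[2], ex[1]))
}

#' Cobb correction rate
#'
#' `100 * (prebrace - inbrace) / prebrace` percent.
#'
#' @param pre Pre-brace Cobb angle, degrees; must be positive.
#' @param inbrace In-brace Cobb angle, degrees.
#' @return Correction rate, percent.
#' @examples
#' correction_rate(40, 20)  # 50
#' @export
correction_rate <- function(pre, inbrace) {
  if (any(pre <= 0)) stop("pre-brace Cobb angle must be positive", call. = FALSE)
  100 * (pre - inbrace) / pre
}

#' Full radiographic report of a geometry
#'
#' Measures the three coronal curves (end vertebrae auto-selected as the
#' maximally tilted vertebrae around each recorded apex, then reported),
#' sagittal TK/LL, apical vertebral translations and axial rotations at
#' the PT and MT apices, and the flatback flag (TK < 10 degrees).
#'
#' @param geometry A `spine_geometry` (reference or deformed).
#' @return A `radiographic_report` list.
#' @export
radiographic_report <- function(geometry) {
  ap <- geometry$apices
  i_pt <- level_index(ap[["pt"]]); i_mt <- level_index(ap[["mt"]])
  i_l <- level_index(ap[["l"]])
  lev <- spine_levels()
  cs <- geometry$concave_side
  flip <- function(side) if (side == "left") "right" else "left"
  ends_pt <- select_end_vertebrae(geometry, ap[["pt"]], 1:i_pt, i_pt:i_mt,
                                  convex = flip(cs[["pt"]]))
  ends_mt <- select_end_vertebrae(geometry, ap[["mt"]], i_pt:i_mt, i_mt:i_l,
                                  convex = flip(cs[["mt"]]))
  ends_l <- select_end_vertebrae(geometry, ap[["l"]], i_mt:i_l,
                                 i_l:level_index("L5"), convex = flip(cs[["l"]]))
  sag <- sagittal_angles(geometry)
  rep_ <- list(
    mt_cobb = cobb_angle(geometry, lev[ends_mt["upper"]], lev[ends_mt["lower"]]),
    pt_cobb = cobb_angle(geometry, lev[ends_pt["upper"]], lev[ends_pt["lower"]]),
    l_cobb = cobb_angle(geometry, lev[ends_l["upper"]], lev[ends_l["lower"]]),
    tk = sag[["tk"]], ll = sag[["ll"]],
    avt_t2 = avt(geometry, ap[["pt"]]), avt_t7 = avt(geometry, ap[["mt"]]),
    axial_rotation_t2 = axial_rotation(vertebra_by_level(geometry, ap[["pt"]])),
    axial_rotation_t7 = axial_rotation(vertebra_by_level(geometry, ap[["mt"]])),
    flatback = sag[["tk"]] < 10 - 1e-6,
    end_vertebrae = list(
      pt = lev[ends_pt], mt = lev[ends_mt], l = lev[ends_l]
    ),
    tk_range = c("T1", "T12"), ll_range = c("L1", "S1")
  )
  class(rep_) <- "radiographic_report"
  rep_
}

#' @export
print.radiographic_report <- function(x, ...) {
  cat(sprintf("Cobb: MT %.1f (%s-%s), PT %.1f (%s-%s), L %.1f (%s-%s) deg\n",
              x$mt_cobb, x$end_vertebrae$mt[1], x$end_vertebrae$mt[2],
              x$pt_cobb, x$end_vertebrae$pt[1], x$end_vertebrae$pt[2],
              x$l_cobb, x$end_vertebrae$l[1], x$end_vertebrae$l[2]))
  cat(sprintf("Sagittal: TK %.1f, LL %.1f deg%s\n", x$tk, x$ll,
              if (x$flatback) " [flatback: TK < 10]" else ""))
  cat(sprintf("AVT: apex PT %+.1f mm, apex MT %+.1f mm; axial rotation %+.1f / %+.1f deg\n",
              x$avt_t2, x$avt_t7, x$axial_rotation_t2, x$axial_rotation_t7))
  invisible(x)
}
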