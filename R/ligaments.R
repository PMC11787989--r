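# Tension-only ligament springs. The tissue table gives only the ligament
# modulus (E = 31.5 MPa) and Poisson ratio; cross-sectional areas are fixed
# per-kind constants (mm^2, literature-informed) and rest lengths are taken
# from the generated geometry, so k = E * A / L per segment.

ligament_kinds <- function() {
  data.frame(
    kind = c("anterior longitudinal", "posterior longitudinal",
             "ligamenta flavum", "supraspinous", "interspinous"),
    area = c(38, 20, 60, 30, 40),        # mm^2
    y_attach = c("anterior", "posterior", "arch", "spinous", "interspinous"),
    stringsAsFactors = FALSE
  )
}

#' Axial stiffness of a ligament segment
#'
#' `k = E * A / L` (N/mm) for a uniaxial spring.
#'
#' @param E Elastic modulus, MPa.
#' @param A Cross-sectional area, mm^2.
#' @param L Rest length, mm; must be positive.
#' @return Stiffness, N/mm.
#' @examples
#' ligament_stiffness(31.5, 10, 10)  # 31.5 N/mm
#' @export
ligament_stiffness <- function(E, A, L) {
  if (L <= 0) stop("ligament rest length must be positive", call. = FALSE)
  if (A <= 0 || E <= 0) stop("ligament E and A must be positive", call. = FALSE)
  E * A / L
}

lig_attach_point <- function(v, where, half, s) {
  # half: +1 = inferior endplate of the upper vertebra, -1 = superior of lower
  zoff <- -half * v$height / 2
  off <- switch(where,
    anterior     = c(0,  v$depth / 2, zoff),
    posterior    = c(0, -v$depth / 2, zoff),
    arch         = c(0, -v$depth / 2 - 14 * s, zoff),
    interspinous = c(0, -v$depth / 2 - 28 * s, zoff),
    spinous      = c(0, -v$depth / 2 - 42 * s, zoff),
    stop("unknown ligament attachment site: ", where, call. = FALSE)
  )
  as.numeric(v$centroid + v$R %*% off)
}

#' Default intervertebral ligament set
#'
#' Instantiates the five modelled ligaments (anterior longitudinal,
#' posterior longitudinal, ligamenta flavum, supraspinous, interspinous) at
#' every vertebral junction as tension-only axial springs. Stiffness is
#' `E * A / L` with the ligament modulus from the material table, a fixed
#' per-kind cross-section, and the rest length taken from the generated
#' geometry.
#'
#' @param geometry A `spine_geometry` (vertebrae already built).
#' @param materials Material table containing a `ligament` entry.
#' @return List of ligament segments: `kind`, `upper_level`, `lower_level`,
#'   `p_upper`, `p_lower`, `rest_length` (mm), `stiffness` (N/mm).
#' @export
default_ligaments <- function(geometry, materials = default_materials()) {
  E <- material_lookup(materials, "ligament")$E
  s <- geometry$params$stature / 152
  kinds <- ligament_kinds()
  n <- length(geometry$vertebrae)
  out <- list()
  for (i in seq_len(n - 1)) {
    up <- geometry$vertebrae[[i]]; lo <- geometry$vertebrae[[i + 1]]
    for (k in seq_len(nrow(kinds))) {
      pu <- lig_attach_point(up, kinds$y_attach[k], +1, s)
      pl <- lig_attach_point(lo, kinds$y_attach[k], -1, s)
      L <- sqrt(sum((pu - pl)^2))
      out[[length(out) + 1]] <- list(
        kind = kinds$kind[k], upper_level = up$level, lower_level = lo$level,
        upper_index = i, lower_index = i + 1,
        p_upper = pu, p_lower = pl,
        rest_length = L, stiffness = ligament_stiffness(E, kinds$area[k], L),
        tension_only = TRUE
      )
    }
  }
  out
}
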