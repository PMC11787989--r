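#' Default tissue material table
#'
#' Literature-based linear-elastic constants for every tissue class in the
#' model: elastic modulus `E` in MPa and Poisson ratio `nu` (dimensionless).
#' Bone and disc constituents are treated as isotropic linear elastic
#' materials; ligaments are tension-only springs whose axial stiffness is
#' derived from the ligament modulus (see [default_ligaments()]).
#'
#' @return A `material_table`: data frame with columns `tissue`, `E` (MPa)
#'   and `nu`, one row per tissue class.
#' @examples
#' mats <- default_materials()
#' material_lookup(mats, "cortical bone")
#' @export
default_materials <- function() {
  tab <- data.frame(
    tissue = c(
      "cortical bone", "cancellous bone", "posterior structure",
      "nucleus pulposus", "annulus fibrosus", "rib", "sternum",
      "pelvis", "sacrum", "costal cartilage", "ligament", "skin"
    ),
    E = c(12000, 100, 3500, 1, 4.2, 5000, 9592, 5000, 5000, 300, 31.5, 31.5),
    nu = c(0.30, 0.20, 0.25, 0.49, 0.45, 0.10, 0.20, 0.20, 0.20, 0.20, 0.45, 0.42),
    stringsAsFactors = FALSE
  )
  class(tab) <- c("material_table", "data.frame")
  tab
}

#' Look up a tissue in a material table
#'
#' @param materials A `material_table` from [default_materials()].
#' @param tissue Tissue name (exact, lower case).
#' @return A list with elements `E` (MPa) and `nu`.
#' @export
material_lookup <- function(materials, tissue) {
  stopifnot(inherits(materials, "material_table"))
  i <- match(tissue, materials$tissue)
  if (is.na(i)) {
    stop("missing material: no entry for tissue '", tissue, "'", call. = FALSE)
  }
  list(E = materials$E[i], nu = materials$nu[i])
}

#' Shear modulus of an isotropic material
#'
#' `G = E / (2 (1 + nu))`.
#'
#' @param E Elastic modulus (MPa).
#' @param nu Poisson ratio.
#' @return Shear modulus (MPa).
#' @export
shear_modulus <- function(E, nu) E / (2 * (1 + nu))

validate_materials <- function(materials) {
  stopifnot(all(materials$E > 0), all(materials$nu >= 0), all(materials$nu < 0.5))
  invisible(materials)
}
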