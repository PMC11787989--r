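# Plain-text interchange: landmark tables (one row per vertebra: level,
# centroid, 8 endplate landmarks) and JSON reports.

#' Export a geometry as a delimited landmark table
#'
#' One row per vertebra: `level`, centroid XYZ, then the four superior and
#' four inferior endplate landmarks (XYZ each), all in mm.
#'
#' @param geometry A `spine_geometry`.
#' @param path Optional file to write (tab-separated).
#' @return The landmark data frame (invisibly when writing).
#' @export
landmark_table <- function(geometry, path = NULL) {
  rows <- lapply(geometry$vertebrae, function(v) {
    lm <- c(t(v$sup), t(v$inf))
    names(lm) <- paste0(rep(c(paste0("sup", 1:4), paste0("inf", 1:4)), each = 3),
                        "_", rep(c("x", "y", "z"), 8))
    data.frame(level = v$level, cx = v$centroid[1], cy = v$centroid[2],
               cz = v$centroid[3], t(lm), stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (!is.null(path)) {
    utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
    return(invisible(tab))
  }
  tab
}

#' Rebuild a measurable geometry from a landmark table
#'
#' Reconstructs vertebra records (centroid, endplate landmarks, orientation
#' from the landmark frame) sufficient for all radiographic measurements.
#' Curve apices and concavity labels default to the reference pattern
#' unless supplied.
#'
#' @param tab Data frame from [landmark_table()] or a path to one.
#' @param apices Named apex levels (`pt`, `mt`, `l`).
#' @param concave_side Named concavity labels per region.
#' @return A `spine_geometry` (without discs, ligaments or muscles).
#' @export
geometry_from_landmarks <- function(tab,
                                    apices = c(pt = "T2", mt = "T7", l = "L2"),
                                    concave_side = c(pt = "right", mt = "left",
                                                     l = "right")) {
  if (is.character(tab)) tab <- utils::read.table(tab, header = TRUE, sep = "\t",
                                                  stringsAsFactors = FALSE)
  vertebrae <- lapply(seq_len(nrow(tab)), function(i) {
    r <- tab[i, ]
    sup <- matrix(as.numeric(r[paste0(rep(paste0("sup", 1:4), each = 3), "_",
                                      rep(c("x", "y", "z"), 4))]), 4, 3, byrow = TRUE)
    inf <- matrix(as.numeric(r[paste0(rep(paste0("inf", 1:4), each = 3), "_",
                                      rep(c("x", "y", "z"), 4))]), 4, 3, byrow = TRUE)
    cen <- as.numeric(r[c("cx", "cy", "cz")])
    ex <- unit3((sup[1, ] + sup[4, ]) / 2 - (sup[2, ] + sup[3, ]) / 2)
    ez <- endplate_normal(sup)
    ey <- crossprod3(ez, ex)
    list(level = r$level, centroid = cen, R = cbind(ex, ey, ez),
         sup = sup, inf = inf,
         width = sqrt(sum((sup[1, ] - sup[2, ])^2)),
         depth = sqrt(sum((sup[1, ] - sup[4, ])^2)),
         height = sqrt(sum((colMeans(sup) - colMeans(inf))^2)))
  })
  g <- list(vertebrae = vertebrae, discs = list(), ligaments = list(),
            muscles = list(), concave_side = concave_side, apices = apices,
            curve_bounds = list(pt = c("T1", "T4"), mt = c("T4", "T11"),
                                l = c("T11", "L4")),
            params = NULL, materials = default_materials())
  class(g) <- "spine_geometry"
  g
}

#' Export sweep tables
#'
#' Writes the per-case summary as TSV and the full metric set as JSON.
#'
#' @param result A `sweep_result`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
export_sweep <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- file.path(dir, "sweep_summary.tsv")
  utils::write.table(sweep_table(result), tsv, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  js <- file.path(dir, "sweep_full.json")
  slim <- lapply(result$cases, function(r) {
    list(radiographic = r$radiographic[c("mt_cobb", "pt_cobb", "l_cobb", "tk",
                                         "ll", "avt_t2", "avt_t7")],
         correction = r$correction,
         disc_height = lapply(r$disc_height, function(d)
           d[c("disc", "region", "height_ratio")]),
         disc_stress = lapply(r$disc_stress, function(d)
           d[c("disc", "region", "stress_ratio")]),
         muscle = list(table = r$muscle$table, overall = r$muscle$overall))
  })
  jsonlite::write_json(list(cases = slim, rankings = result$rankings,
                            provenance = result$provenance),
                       js, auto_unbox = TRUE, digits = 8, pretty = TRUE)
  invisible(c(tsv, js))
}
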