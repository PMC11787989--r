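# Bilateral trunk muscle fascicle set. Paravertebral extensors (MF, LG, IC)
# attach segmentally to posterior vertebral landmarks; QL/PM/IP run between
# the lateral lumbar spine and the pelvis/femur; RA/EO/IO are anchored to an
# elliptical torso cross-section centred on the vertebral column. PCSA
# values (mm^2) are literature-informed per-fascicle constants.

torso_ellipse <- function(s) c(a = 110 * s, b = 85 * s)  # semi-axes, mm

muscle_point <- function(v, x, y, z = 0) {
  as.numeric(v$centroid + v$R %*% c(x, y, z))
}

new_fascicle <- function(name, side, origin, insertion, origin_index,
                         insertion_index, pcsa) {
  # origin is always the cranial attachment
  list(name = name, side = side, origin = origin, insertion = insertion,
       origin_index = origin_index, insertion_index = insertion_index,
       pcsa = pcsa,
       length = sqrt(sum((origin - insertion)^2)))
}

#' Default bilateral trunk muscle fascicle set
#'
#' Eleven muscle groups on each side: multifidus (MF), longissimus thoracis
#' pars thoracis/lumborum (LGPT/LGPL), iliocostalis pars thoracis/lumborum
#' (ICPT/ICPL), quadratus lumborum (QL), psoas major (PM), iliopsoas (IP),
#' rectus abdominis (RA), external and internal obliques (EO, IO).
#' Fascicles are straight chords between attachment points that follow the
#' vertebral landmarks, so scoliotic geometry asymmetry is inherited by the
#' fascicle paths and lengths.
#'
#' @param geometry A `spine_geometry`.
#' @return List of fascicles, each with `name`, `side` (`"left"`/`"right"`),
#'   `origin`/`insertion` (mm, origin cranial), attachment vertebra indices,
#'   `pcsa` (mm^2) and chord `length` (mm).
#' @export
default_muscles <- function(geometry) {
  s <- geometry$params$stature / 152
  V <- geometry$vertebrae
  n <- length(V)
  iS1 <- n
  S1 <- V[[iS1]]
  fas <- list()
  add <- function(f) fas[[length(fas) + 1L]] <<- f

  for (side in c("left", "right")) {
    sg <- if (side == "right") 1 else -1

    # multifidus: short segmental bridges spanning two junctions
    for (i in 1:(n - 2)) {
      j <- min(i + 2, iS1)
      add(new_fascicle("MF", side,
        muscle_point(V[[i]], sg * 8 * s, -(V[[i]]$depth / 2 + 12 * s)),
        muscle_point(V[[j]], sg * 8 * s, -(V[[j]]$depth / 2 + 12 * s)),
        i, j, pcsa = 90))
    }
    # longissimus pars thoracis: each thoracic level to a sacral anchor
    for (i in 1:12) {
      add(new_fascicle("LGPT", side,
        muscle_point(V[[i]], sg * 20 * s, -(V[[i]]$depth / 2 + 18 * s)),
        muscle_point(S1, sg * 25 * s, -(S1$depth / 2 + 18 * s)),
        i, iS1, pcsa = 60))
    }
    # longissimus pars lumborum: each lumbar level to the sacrum/ilium
    for (i in 13:17) {
      add(new_fascicle("LGPL", side,
        muscle_point(V[[i]], sg * 25 * s, -(V[[i]]$depth / 2 + 18 * s)),
        muscle_point(S1, sg * 30 * s, -(S1$depth / 2 + 15 * s), -20 * s),
        i, iS1, pcsa = 110))
    }
    # iliocostalis pars thoracis: lower thoracic (rib angles) to the ilium
    for (i in 5:12) {
      add(new_fascicle("ICPT", side,
        muscle_point(V[[i]], sg * 35 * s, -(V[[i]]$depth / 2 + 10 * s)),
        muscle_point(S1, sg * 45 * s, -(S1$depth / 2 + 5 * s), -10 * s),
        i, iS1, pcsa = 60))
    }
    # iliocostalis pars lumborum
    for (i in 13:16) {
      add(new_fascicle("ICPL", side,
        muscle_point(V[[i]], sg * 40 * s, -(V[[i]]$depth / 2 + 8 * s)),
        muscle_point(S1, sg * 50 * s, -S1$depth / 2, -15 * s),
        i, iS1, pcsa = 100))
    }
    # quadratus lumborum: T12 / upper lumbar lateral mass to the iliac crest
    add(new_fascicle("QL", side,
      muscle_point(V[[12]], sg * 40 * s, -5 * s),
      muscle_point(S1, sg * 50 * s, 0, -10 * s),
      12, iS1, pcsa = 90))
    # psoas major: each lumbar body, anterolateral, to the proximal femur
    femur <- muscle_point(S1, sg * 40 * s, 40 * s, -90 * s)
    for (i in 13:17) {
      add(new_fascicle("PM", side,
        muscle_point(V[[i]], sg * 22 * s, V[[i]]$depth * 0.3),
        femur, i, iS1, pcsa = 120))
    }
    # iliopsoas (iliacus path): L4 to the femur
    add(new_fascicle("IP", side,
      muscle_point(V[[16]], sg * 25 * s, V[[16]]$depth * 0.4),
      femur, 16, iS1, pcsa = 250))

    # abdominal wall on the torso ellipse
    el <- torso_ellipse(s)
    i_rib <- 9  # costal margin level (T9)
    add(new_fascicle("RA", side,
      muscle_point(V[[i_rib]], sg * 30 * s, el[["b"]]),
      muscle_point(S1, sg * 30 * s, 70 * s, -60 * s),
      i_rib, iS1, pcsa = 270))
    add(new_fascicle("EO", side,
      muscle_point(V[[i_rib]], sg * el[["a"]] * cos(deg2rad(40)),
                   el[["b"]] * sin(deg2rad(40))),
      muscle_point(S1, sg * 15 * s, 75 * s, -40 * s),
      i_rib, iS1, pcsa = 190))
    add(new_fascicle("IO", side,
      muscle_point(V[[12]], sg * 20 * s, 60 * s),
      muscle_point(S1, sg * el[["a"]] * cos(deg2rad(35)) * 0.55,
                   30 * s, -25 * s),
      12, iS1, pcsa = 180))
  }
  fas
}

#' Muscle fascicle summary table
#'
#' @param muscles Fascicle list from [default_muscles()].
#' @return Data frame: one row per fascicle with group, side, PCSA and
#'   chord length.
#' @export
muscle_table <- function(muscles) {
  data.frame(
    name = vapply(muscles, `[[`, "", "name"),
    side = vapply(muscles, `[[`, "", "side"),
    origin_index = vapply(muscles, function(m) as.integer(m$origin_index), 0L),
    insertion_index = vapply(muscles, function(m) as.integer(m$insertion_index), 0L),
    pcsa = vapply(muscles, `[[`, 0, "pcsa"),
    length = vapply(muscles, `[[`, 0, "length"),
    stringsAsFactors = FALSE
  )
}
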