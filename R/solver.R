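# Reduced-order statics: rigid vertebrae connected by elastic 6-DOF disc
# joints and tension-only ligament springs. State vector per vertebra:
# translation u (mm) and rotation theta (rad), global frame. Assembly is
# dense (at most 18 x 6 = 108 DOF), solved by direct factorization.

#' Default solver calibration constants
#'
#' `bend_scale` multiplies the bare-disc rotational stiffness `E I / h`
#' (and torsion) to account for posterior elements, facet joints and
#' ribcage stiffening that the isolated disc column lacks; its default is
#' fixed from segmental range-of-motion realism (a few degrees per segment
#' under a 4 N m pure moment). `sigma_max` (MPa) bounds muscle stress;
#' `tone` (MPa) is the symmetric resting activation stress added to every
#' fascicle after optimization.
#'
#' `load_updates` is the number of quasi-static load-position updates used
#' by the study pipeline (see `update_loads` in [solve_static()]): the
#' gravity, patch and muscle application points follow the deforming spine,
#' capturing the second-order moment-arm changes of large corrections.
#'
#' @return Named list of calibration constants.
#' @export
default_calibration <- function() {
  list(bend_scale = 30, sigma_max = 0.5, tone = 0.01, load_updates = 2)
}

#' Elastic joint stiffness of one disc
#'
#' Diagonal 6x6 joint stiffness in the disc local frame from the
#' area-weighted annulus/nucleus modulus: axial `E_eff A / h`, shear
#' `G A / h`, bending `c E_eff I / h` about both lateral axes and torsion
#' `c G J / h`, with `c` the documented `bend_scale` calibration.
#'
#' @param disc A disc record from a `spine_geometry`.
#' @param materials Material table.
#' @param calibration See [default_calibration()].
#' @return List with `Kf`, `Km` (3x3, global frame), local diagonal terms,
#'   section properties `A`, `Ix`, `Iy`, `J` and `E_eff`.
#' @export
disc_stiffness <- function(disc, materials = default_materials(),
                           calibration = default_calibration()) {
  ann <- material_lookup(materials, disc$annulus)
  nuc <- material_lookup(materials, disc$nucleus)
  fn <- disc$nucleus_fraction
  E_eff <- (1 - fn) * ann$E + fn * nuc$E
  nu_eff <- (1 - fn) * ann$nu + fn * nuc$nu
  G_eff <- shear_modulus(E_eff, nu_eff)
  A <- pi * disc$a * disc$b
  Ix <- pi / 4 * disc$a * disc$b^3   # bending about local x (sagittal plane)
  Iy <- pi / 4 * disc$b * disc$a^3   # bending about local y (coronal plane)
  J <- Ix + Iy
  h <- disc$height
  c_ <- calibration$bend_scale
  k_loc_f <- c(G_eff * A / h, G_eff * A / h, E_eff * A / h)
  k_loc_m <- c(c_ * E_eff * Ix / h, c_ * E_eff * Iy / h, c_ * G_eff * J / h)
  Rd <- disc$R
  list(
    Kf = Rd %*% diag(k_loc_f) %*% t(Rd),
    Km = Rd %*% diag(k_loc_m) %*% t(Rd),
    k_local_force = k_loc_f, k_local_moment = k_loc_m,
    A = A, Ix = Ix, Iy = Iy, J = J, E_eff = E_eff, h = h
  )
}

# 3x6 kinematic map giving the displacement of the material point at `point`
# on a rigid body with reference centroid `centroid`.
point_map <- function(point, centroid) {
  cbind(diag(3), -skew(point - centroid))
}

#' Assemble the reduced-order stiffness model
#'
#' One 6-DOF elastic joint per disc plus one tension-only axial spring per
#' ligament segment. Before boundary conditions the assembled stiffness has
#' exactly the six rigid-body modes in its nullspace.
#'
#' @param geometry A `spine_geometry`.
#' @param materials Material table.
#' @param calibration See [default_calibration()].
#' @return A `spine_model`: geometry, per-disc element data, ligament
#'   element data, the disc-only global stiffness `K_disc`, and `ndof`.
#' @export
assemble_model <- function(geometry, materials = geometry$materials,
                           calibration = default_calibration()) {
  V <- geometry$vertebrae
  n <- length(V)
  ndof <- 6 * n
  K <- matrix(0, ndof, ndof)
  dofs <- function(i) (6 * (i - 1) + 1):(6 * i)

  lev <- vapply(V, `[[`, "", "level")
  disc_elems <- vector("list", length(geometry$discs))
  for (e in seq_along(geometry$discs)) {
    dsc <- geometry$discs[[e]]
    iu <- match(dsc$upper_level, lev)
    il <- iu + 1
    if (!identical(V[[il]]$level, dsc$lower_level)) {
      stop("non-consecutive disc levels: ", dsc$upper_level, "/", dsc$lower_level,
           call. = FALSE)
    }
    ks <- disc_stiffness(dsc, materials, calibration)
    Bu <- point_map(dsc$center, V[[iu]]$centroid)
    Bl <- point_map(dsc$center, V[[il]]$centroid)
    Gu <- cbind(matrix(0, 3, 3), diag(3))
    # element stiffness on [x_u; x_l]
    Krel_f <- function(Ba, Bb) t(Ba) %*% ks$Kf %*% Bb
    Krel_m <- function(Ga, Gb) t(Ga) %*% ks$Km %*% Gb
    du <- dofs(iu); dl <- dofs(il)
    K[du, du] <- K[du, du] + Krel_f(Bu, Bu) + Krel_m(Gu, Gu)
    K[dl, dl] <- K[dl, dl] + Krel_f(Bl, Bl) + Krel_m(Gu, Gu)
    K[du, dl] <- K[du, dl] - Krel_f(Bu, Bl) - Krel_m(Gu, Gu)
    K[dl, du] <- K[dl, du] - Krel_f(Bl, Bu) - Krel_m(Gu, Gu)
    disc_elems[[e]] <- list(iu = iu, il = il, Bu = Bu, Bl = Bl,
                            stiff = ks, disc = dsc)
  }

  lig_elems <- lapply(geometry$ligaments, function(lg) {
    iu <- lg$upper_index; il <- lg$lower_index
    nvec <- unit3(lg$p_upper - lg$p_lower)
    Bu <- t(nvec) %*% point_map(lg$p_upper, V[[iu]]$centroid)  # 1x6
    Bl <- t(nvec) %*% point_map(lg$p_lower, V[[il]]$centroid)
    list(iu = iu, il = il, Bu = Bu, Bl = Bl, k = lg$stiffness,
         kind = lg$kind, upper_level = lg$upper_level)
  })

  structure(list(geometry = geometry, materials = materials,
                 calibration = calibration, n = n, ndof = ndof,
                 K_disc = K, disc_elems = disc_elems, lig_elems = lig_elems),
            class = "spine_model")
}

lig_K_contrib <- function(K, le, dofs) {
  du <- dofs(le$iu); dl <- dofs(le$il)
  kBuBu <- le$k * (t(le$Bu) %*% le$Bu)
  kBlBl <- le$k * (t(le$Bl) %*% le$Bl)
  kBuBl <- le$k * (t(le$Bu) %*% le$Bl)
  K[du, du] <- K[du, du] + kBuBu
  K[dl, dl] <- K[dl, dl] + kBlBl
  K[du, dl] <- K[du, dl] - kBuBl
  K[dl, du] <- K[dl, du] - t(kBuBl)
  K
}

# Boundary-condition DOF indices for the standing model: sacrum fully
# fixed; T1 free to bend laterally (coronal sway u_x and rotation),
# bend forward (sagittal rotation) and extend vertically (u_z);
# anterior-posterior translation and axial rotation restrained.
standing_fixed_dofs <- function(model) {
  n <- model$n
  s1 <- (6 * (n - 1) + 1):(6 * n)
  t1 <- c(2, 6)  # u_y and theta_z of the first (cranial) vertebra
  c(t1, s1)
}

# Generalized load vector. Moments are always taken about the reference
# centroids (the DOF reference); `app_geometry` supplies the application
# points, so passing a deformed geometry realises a load-position update.
build_load_vector <- function(model, loadcase, muscle_forces = NULL,
                              app_geometry = model$geometry) {
  V <- model$geometry$vertebrae
  Va <- app_geometry$vertebrae
  n <- model$n
  f <- numeric(model$ndof)
  lev <- vapply(V, `[[`, "", "level")
  add_force <- function(f, i, F, point) {
    d <- (6 * (i - 1) + 1):(6 * i)
    f[d[1:3]] <- f[d[1:3]] + F
    f[d[4:6]] <- f[d[4:6]] + crossprod3(point - V[[i]]$centroid, F)
    f
  }
  if (!is.null(loadcase$gravity)) {
    g <- loadcase$gravity
    for (r in seq_len(nrow(g))) {
      i <- match(g$level[r], lev)
      if (is.na(i)) next
      f <- add_force(f, i, c(0, 0, -g$force[r]), Va[[i]]$centroid)
    }
  }
  for (p in loadcase$patches) {
    per <- p$force / length(p$targets)
    for (k in seq_along(p$targets)) {
      i <- match(p$targets[k], lev)
      if (is.na(i)) next
      f <- add_force(f, i, per * p$direction, p$points[[k]])
    }
  }
  if (!is.null(muscle_forces)) {
    mus <- if (length(app_geometry$muscles) == length(muscle_forces$fascicles))
      app_geometry$muscles else muscle_forces$fascicles
    tension <- muscle_forces$force
    for (k in seq_along(mus)) {
      if (tension[k] <= 0) next
      m <- mus[[k]]
      u <- unit3(m$insertion - m$origin)
      if (m$origin_index <= n) {
        f <- add_force(f, m$origin_index, tension[k] * u, m$origin)
      }
      if (m$insertion_index <= n) {
        f <- add_force(f, m$insertion_index, -tension[k] * u, m$insertion)
      }
    }
  }
  f
}

crossprod3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

#' Solve static equilibrium under a load case
#'
#' Direct solve of the constrained linear system, with the tension-only
#' ligament set resolved by active-set fixed-point iteration (a ligament is
#' active only while elongated; at most `max_iter` passes). Optionally
#' includes optimized muscle forces as constant-direction point loads at
#' their attachment chords.
#'
#' @param model A `spine_model` from [assemble_model()].
#' @param loadcase A `load_case`.
#' @param muscle_forces Optional result of [optimize_muscle_forces()].
#' @param fixed_dofs Constrained DOF indices; default standing boundary
#'   conditions (sacrum fixed, T1 bending/vertical-translation free).
#' @param max_iter,tol Active-set iteration controls.
#' @param update_loads Number of quasi-static load-position updates: after
#'   each solve the gravity, patch and muscle application points are moved
#'   to the deformed configuration and the system is re-solved about the
#'   reference state. `0` (default) is the strictly linear operation;
#'   2--3 updates capture the second-order moment-arm changes of large
#'   corrections.
#' @return An `equilibrium_state`: `u` (n x 3 mm), `theta` (n x 3 rad),
#'   per-disc internal wrench in the disc local frame (`N` axial force,
#'   compression negative; shear `Vx`, `Vy`; moments `Mx`, `My`, `T`,
#'   N mm), ligament tensions, reaction wrench at the constraints,
#'   `residual` norm, `converged`, and the `deformed` geometry.
#' @export
solve_static <- function(model, loadcase, muscle_forces = NULL,
                         fixed_dofs = standing_fixed_dofs(model),
                         max_iter = 50, tol = 1e-8, update_loads = 0) {
  ndof <- model$ndof
  dofs <- function(i) (6 * (i - 1) + 1):(6 * i)
  free <- setdiff(seq_len(ndof), fixed_dofs)
  if (length(free) == 0) stop("all degrees of freedom are fixed", call. = FALSE)

  solve_pass <- function(f, active) {
    x <- numeric(ndof)
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      K <- model$K_disc
      for (j in seq_along(model$lig_elems)) {
        if (active[j]) K <- lig_K_contrib(K, model$lig_elems[[j]], dofs)
      }
      Kff <- K[free, free, drop = FALSE]
      x[] <- 0
      sol <- tryCatch(solve(Kff, f[free]),
                      error = function(e) stop("singular constrained system: ",
                                               conditionMessage(e), call. = FALSE))
      x[free] <- sol
      elong <- vapply(model$lig_elems, function(le) {
        as.numeric(le$Bu %*% x[dofs(le$iu)] - le$Bl %*% x[dofs(le$il)])
      }, 0)
      new_active <- elong > -tol
      if (all(new_active == active)) { converged <- TRUE; break }
      active <- new_active
    }
    list(x = x, active = active, converged = converged)
  }

  f <- build_load_vector(model, loadcase, muscle_forces)
  pass <- solve_pass(f, rep(TRUE, length(model$lig_elems)))
  if (update_loads > 0) {
    for (k in seq_len(update_loads)) {
      u_k <- matrix(pass$x, ncol = 6, byrow = TRUE)[, 1:3, drop = FALSE]
      th_k <- matrix(pass$x, ncol = 6, byrow = TRUE)[, 4:6, drop = FALSE]
      gdef <- deform_geometry(model$geometry, u_k, th_k)
      lc_k <- loadcase
      lc_k$patches <- lapply(loadcase$patches, function(p)
        pressure_patch(p$region, p$pressure, gdef))
      f <- build_load_vector(model, lc_k, muscle_forces, app_geometry = gdef)
      pass <- solve_pass(f, pass$active)
    }
  }
  x <- pass$x
  active <- pass$active
  converged <- pass$converged
  K <- model$K_disc
  for (j in seq_along(model$lig_elems)) {
    if (active[j]) K <- lig_K_contrib(K, model$lig_elems[[j]], dofs)
  }
  resid <- K[free, , drop = FALSE] %*% x - f[free]
  reaction <- as.numeric(K[fixed_dofs, , drop = FALSE] %*% x - f[fixed_dofs])

  n <- model$n
  u <- matrix(x, ncol = 6, byrow = TRUE)[, 1:3, drop = FALSE]
  th <- matrix(x, ncol = 6, byrow = TRUE)[, 4:6, drop = FALSE]

  wrench <- lapply(model$disc_elems, function(de) {
    xu <- x[dofs(de$iu)]; xl <- x[dofs(de$il)]
    drel <- as.numeric(de$Bu %*% xu - de$Bl %*% xl)
    grel <- xu[4:6] - xl[4:6]
    F_on_lower <- as.numeric(de$stiff$Kf %*% drel)   # force transmitted to the lower body
    M_on_lower <- as.numeric(de$stiff$Km %*% grel)
    loc_f <- as.numeric(t(de$disc$R) %*% F_on_lower)
    loc_m <- as.numeric(t(de$disc$R) %*% M_on_lower)
    list(upper_level = de$disc$upper_level, lower_level = de$disc$lower_level,
         Vx = loc_f[1], Vy = loc_f[2], N = loc_f[3],   # compression negative
         Mx = loc_m[1], My = loc_m[2], T = loc_m[3],
         force_global = F_on_lower, moment_global = M_on_lower)
  })

  lig_tension <- vapply(seq_along(model$lig_elems), function(j) {
    if (!active[j]) return(0)
    le <- model$lig_elems[[j]]
    as.numeric(le$k * (le$Bu %*% x[dofs(le$iu)] - le$Bl %*% x[dofs(le$il)]))
  }, 0)

  state <- structure(list(
    u = u, theta = th, x = x, f = f, wrench = wrench,
    ligament_tension = lig_tension, ligament_active = active,
    reaction = reaction, fixed_dofs = fixed_dofs,
    residual = sqrt(sum(resid^2)), converged = converged,
    load_label = loadcase$label, muscle_forces = muscle_forces,
    model = model
  ), class = "equilibrium_state")
  state$deformed <- deform_geometry(model$geometry, u, th)
  state
}

#' Apply a solved displacement field to a geometry
#'
#' Rigid-vertebra update: centroids translate by `u`; orientations are
#' premultiplied by the finite rotation of each rotation vector. Endplate
#' landmarks and disc frames are rebuilt; ligaments and muscles are
#' regenerated from the deformed landmarks.
#'
#' @param geometry A `spine_geometry`.
#' @param u,theta n x 3 matrices of translations (mm) and rotation
#'   vectors (rad).
#' @return The deformed `spine_geometry`.
#' @export
deform_geometry <- function(geometry, u, theta) {
  g <- geometry
  n <- length(g$vertebrae)
  for (i in seq_len(n)) {
    v <- g$vertebrae[[i]]
    Rn <- rot_vec(theta[i, ]) %*% v$R
    cen <- v$centroid + u[i, ]
    corners <- rbind(c(1, 1), c(-1, 1), c(-1, -1), c(1, -1))
    v$centroid <- cen; v$R <- Rn
    v$sup <- t(apply(corners, 1, function(cc)
      cen + Rn %*% c(cc[1] * v$width / 2, cc[2] * v$depth / 2, v$height / 2)))
    v$inf <- t(apply(corners, 1, function(cc)
      cen + Rn %*% c(cc[1] * v$width / 2, cc[2] * v$depth / 2, -v$height / 2)))
    nrm <- Rn %*% c(0, 0, 1)
    v$coronal_tilt <- rad2deg(atan2(nrm[1], nrm[3]))
    v$sagittal_tilt <- rad2deg(atan2(nrm[2], nrm[3]))
    ex <- Rn %*% c(1, 0, 0)
    v$axial_rotation <- rad2deg(atan2(ex[2], ex[1]))
    g$vertebrae[[i]] <- v
  }
  for (e in seq_along(g$discs)) {
    dsc <- g$discs[[e]]
    up <- g$vertebrae[[e]]; lo <- g$vertebrae[[e + 1]]
    c_up <- colMeans(up$inf); c_lo <- colMeans(lo$sup)
    dsc$center <- (c_up + c_lo) / 2
    axis <- unit3(c_up - c_lo)
    xd <- (up$R[, 1] + lo$R[, 1]) / 2
    xd <- unit3(xd - sum(xd * axis) * axis)
    yd <- crossprod3(axis, xd)
    dsc$R <- cbind(xd, yd, axis)
    g$discs[[e]] <- dsc
  }
  g$ligaments <- default_ligaments(g, g$materials)
  g$muscles <- default_muscles(g)
  g
}

#' Extract a consecutive sub-chain of a spine geometry
#'
#' Keeps vertebrae from `from` to `to` (cranial to caudal) together with
#' the discs and ligaments between them; muscles are dropped.
#'
#' @param geometry A `spine_geometry`.
#' @param from,to Level labels.
#' @return A reduced `spine_geometry`.
#' @export
subchain <- function(geometry, from, to) {
  i0 <- level_index(from); i1 <- level_index(to)
  stopifnot(i0 < i1)
  g <- geometry
  g$vertebrae <- geometry$vertebrae[i0:i1]
  g$discs <- geometry$discs[i0:(i1 - 1)]
  g$ligaments <- Filter(function(lg) lg$upper_index >= i0 && lg$lower_index <= i1,
                        geometry$ligaments)
  g$ligaments <- lapply(g$ligaments, function(lg) {
    lg$upper_index <- lg$upper_index - i0 + 1
    lg$lower_index <- lg$lower_index - i0 + 1
    lg
  })
  g$muscles <- list()
  g
}

#' Range of motion of a spinal segment under a pure moment
#'
#' All DOF of the caudal `fixed_level` are constrained; a pure moment of
#' the given magnitude and direction is applied to `loaded_level`; ROM is
#' the rotation of the loaded vertebra about the moment axis, in degrees.
#'
#' @param geometry A `spine_geometry`.
#' @param materials Material table.
#' @param fixed_level,loaded_level Level labels (`fixed_level` caudal).
#' @param moment Applied moment, N m.
#' @param direction One of `"flexion"`, `"extension"`,
#'   `"left lateral bending"`, `"right lateral bending"`,
#'   `"left axial rotation"`, `"right axial rotation"`.
#' @param calibration See [default_calibration()].
#' @return A `rom_result` list: segment, direction, moment, `rom` degrees.
#' @export
rom_test <- function(geometry, materials = geometry$materials,
                     fixed_level = "T4", loaded_level = "T1", moment = 4,
                     direction = "flexion",
                     calibration = default_calibration()) {
  if (level_index(fixed_level) <= level_index(loaded_level)) {
    stop("fixed_level must be caudal to loaded_level", call. = FALSE)
  }
  sub <- subchain(geometry, loaded_level, fixed_level)
  axis <- switch(direction,
    "flexion" = c(-1, 0, 0), "extension" = c(1, 0, 0),
    "right lateral bending" = c(0, 1, 0), "left lateral bending" = c(0, -1, 0),
    "right axial rotation" = c(0, 0, -1), "left axial rotation" = c(0, 0, 1),
    stop("unknown ROM direction: ", direction, call. = FALSE))
  model <- assemble_model(sub, materials, calibration)
  n <- model$n
  fixed <- (6 * (n - 1) + 1):(6 * n)
  f <- numeric(model$ndof)
  f[4:6] <- axis * moment * 1000  # N m -> N mm, pure moment on loaded vertebra
  st <- solve_static_custom(model, f, fixed)
  rot <- sum(st$theta[1, ] * axis)
  structure(list(segment = paste(loaded_level, fixed_level, sep = "-"),
                 direction = direction, moment = moment,
                 rom = max(rad2deg(rot), 0), state = st),
            class = "rom_result")
}

# solve with an explicit load vector (internal; shares the active-set loop)
solve_static_custom <- function(model, f, fixed_dofs, max_iter = 50, tol = 1e-8) {
  dofs <- function(i) (6 * (i - 1) + 1):(6 * i)
  free <- setdiff(seq_len(model$ndof), fixed_dofs)
  active <- rep(TRUE, length(model$lig_elems))
  x <- numeric(model$ndof)
  for (it in seq_len(max_iter)) {
    K <- model$K_disc
    for (j in seq_along(model$lig_elems)) {
      if (active[j]) K <- lig_K_contrib(K, model$lig_elems[[j]], dofs)
    }
    x[] <- 0
    x[free] <- solve(K[free, free, drop = FALSE], f[free])
    elong <- vapply(model$lig_elems, function(le) {
      as.numeric(le$Bu %*% x[dofs(le$iu)] - le$Bl %*% x[dofs(le$il)])
    }, 0)
    new_active <- elong > -tol
    if (all(new_active == active)) break
    active <- new_active
  }
  list(x = x, u = matrix(x, ncol = 6, byrow = TRUE)[, 1:3, drop = FALSE],
       theta = matrix(x, ncol = 6, byrow = TRUE)[, 4:6, drop = FALSE],
       active = active)
}

#' Subdivide each disc joint into serial sub-joints
#'
#' Refinement harness for the reduced-order discretization: every disc is
#' replaced by `n` serial elastic joints of height `h/n` separated by
#' massless rigid interface bodies. Loads map by level label, so the
#' interface bodies carry none. Reported displacements converge as `n`
#' grows (the discretization-refinement check).
#'
#' @param geometry A `spine_geometry`.
#' @param n Number of serial sub-joints per disc (>= 1).
#' @return A `spine_geometry` with interface bodies and sub-discs;
#'   ligaments are re-indexed, muscles dropped.
#' @export
subdivide_discs <- function(geometry, n) {
  stopifnot(n >= 1)
  if (n == 1) return(geometry)
  V <- geometry$vertebrae
  newV <- list()
  newD <- list()
  for (i in seq_along(V)) {
    newV[[length(newV) + 1]] <- V[[i]]
    if (i == length(V)) break
    dsc <- geometry$discs[[i]]
    up <- V[[i]]; lo <- V[[i + 1]]
    q1 <- colMeans(up$inf); q0 <- colMeans(lo$sup)  # top / bottom disc faces
    names_j <- paste0(dsc$upper_level, ":", seq_len(n - 1))
    for (j in seq_len(n - 1)) {
      cen <- q1 + (q0 - q1) * (j / n)
      corners <- rbind(c(1, 1), c(-1, 1), c(-1, -1), c(1, -1))
      lm <- t(apply(corners, 1, function(cc)
        cen + dsc$R %*% c(cc[1] * dsc$a, cc[2] * dsc$b, 0)))
      newV[[length(newV) + 1]] <- list(
        level = names_j[j], centroid = cen, R = dsc$R,
        width = 2 * dsc$a, depth = 2 * dsc$b, height = 0,
        sup = lm, inf = lm,
        coronal_tilt = NA_real_, sagittal_tilt = NA_real_,
        axial_rotation = NA_real_)
    }
    chain <- c(dsc$upper_level, names_j, dsc$lower_level)
    for (k in seq_len(n)) {
      sub <- dsc
      sub$upper_level <- chain[k]
      sub$lower_level <- chain[k + 1]
      sub$height <- dsc$height / n
      sub$center <- q1 + (q0 - q1) * ((k - 0.5) / n)
      newD[[length(newD) + 1]] <- sub
    }
  }
  g <- geometry
  g$vertebrae <- newV
  g$discs <- newD
  lev_new <- vapply(newV, `[[`, "", "level")
  g$ligaments <- lapply(geometry$ligaments, function(lg) {
    lg$upper_index <- match(lg$upper_level, lev_new)
    lg$lower_index <- match(lg$lower_level, lev_new)
    lg
  })
  g$muscles <- list()
  g
}
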