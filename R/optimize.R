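# Static optimization of muscle forces: minimize the sum of squared muscle
# stresses sum (f_i / PCSA_i)^2 subject to non-negative tension, the
# sigma_max * PCSA capacity bound, and lateral/sagittal moment balance of
# the free body above every instrumented disc level. The quadratic program
# is solved in stress variables g = f / PCSA by Lawson-Hanson NNLS
# (pracma::lsqnonneg) with heavily weighted equality rows; capacity bounds
# are enforced by an outer active-set pass.

# External (gravity + patch) moment about each disc center from the free
# body of all vertebrae cranial to the disc. Rows: discs; cols: Mx, My, Mz
# (N mm, global frame).
external_disc_moments <- function(geometry, loadcase) {
  V <- geometry$vertebrae
  lev <- vapply(V, `[[`, "", "level")
  n_d <- length(geometry$discs)
  M <- matrix(0, n_d, 3)
  forces <- list()  # list of (index, point, F)
  if (!is.null(loadcase$gravity)) {
    g <- loadcase$gravity
    for (r in seq_len(nrow(g))) {
      i <- match(g$level[r], lev)
      if (is.na(i)) next
      forces[[length(forces) + 1]] <- list(i = i, p = V[[i]]$centroid,
                                           F = c(0, 0, -g$force[r]))
    }
  }
  for (p in loadcase$patches) {
    per <- p$force / length(p$targets)
    for (k in seq_along(p$targets)) {
      i <- match(p$targets[k], lev)
      if (is.na(i)) next
      forces[[length(forces) + 1]] <- list(i = i, p = p$points[[k]],
                                           F = per * p$direction)
    }
  }
  for (j in seq_len(n_d)) {
    cj <- geometry$discs[[j]]$center
    for (fr in forces) {
      if (fr$i <= j) M[j, ] <- M[j, ] + crossprod3(fr$p - cj, fr$F)
    }
  }
  M
}

# Moment arm coefficients: a[j, i, ] = moment about disc j per unit tension
# of fascicle i (zero unless the fascicle crosses disc j).
muscle_moment_arms <- function(geometry, fascicles) {
  n_d <- length(geometry$discs)
  n_m <- length(fascicles)
  A <- array(0, dim = c(n_d, n_m, 3))
  for (i in seq_len(n_m)) {
    m <- fascicles[[i]]
    u <- unit3(m$insertion - m$origin)
    for (j in seq_len(n_d)) {
      if (m$origin_index <= j && m$insertion_index >= j + 1) {
        A[j, i, ] <- crossprod3(m$origin - geometry$discs[[j]]$center, u)
      }
    }
  }
  A
}

# Equality-constrained non-negative least-norm QP in stress variables.
# Minimize ||g||^2 subject to C g = b (soft, weighted), 0 <= g <= cap.
solve_muscle_qp <- function(C, b, cap, weight = 1e4) {
  n <- ncol(C)
  scale <- max(abs(b), apply(abs(C), 1, max), 1)
  Cw <- C / scale * weight
  bw <- b / scale * weight
  fixed <- rep(FALSE, n)
  g <- numeric(n)
  for (pass in 1:25) {
    free <- which(!fixed)
    if (length(free) == 0) break
    b_eff <- bw - if (any(fixed)) Cw[, fixed, drop = FALSE] %*% g[fixed] else 0
    A <- rbind(Cw[, free, drop = FALSE], diag(length(free)))
    rhs <- c(as.numeric(b_eff), numeric(length(free)))
    sol <- pracma::lsqnonneg(A, rhs)
    g[free] <- sol$x
    over <- g > cap + 1e-9
    if (!any(over & !fixed)) break
    fixed <- fixed | over
    g[g > cap] <- cap[g > cap]
  }
  resid <- as.numeric(C %*% g - b)
  list(g = g, residual = sqrt(sum(resid^2)),
       rel_residual = sqrt(sum(resid^2)) / max(sqrt(sum(b^2)), 1e-12))
}

#' Optimize muscle fascicle forces for static balance
#'
#' Chooses non-negative fascicle tensions minimizing the summed squared
#' muscle stress `sum (f_i / PCSA_i)^2` subject to the capacity bound
#' `f_i <= sigma_max * PCSA_i` and moment balance (coronal and sagittal
#' components) of the free body above every instrumented disc. After
#' optimization a symmetric resting tone `tone * PCSA` is added to every
#' fascicle, so perfectly symmetric problems report exact unit
#' concave/convex ratios.
#'
#' @param geometry A `spine_geometry` (fascicle moment arms are taken from
#'   its current, possibly deformed, landmarks).
#' @param loadcase A `load_case`; its gravity and patch forces form the
#'   external moments to balance.
#' @param fascicles Fascicle set; defaults to `geometry$muscles`.
#' @param instrumented Disc indices at which balance is enforced; default
#'   all discs.
#' @param calibration See [default_calibration()] (`sigma_max`, `tone`).
#' @param balance_tol Relative moment-residual above which the problem is
#'   flagged infeasible. The default accepts the least-squares compromise
#'   left by fascicle coupling and capacity bounds (carried physically by
#'   the passive column and the cranial boundary), flagging only gross
#'   imbalance.
#' @return A `muscle_forces` object: `fascicles`, `force` (N, tone
#'   included), `force_optimized` (N, tone excluded), `rel_residual`,
#'   `converged`.
#' @export
optimize_muscle_forces <- function(geometry, loadcase,
                                   fascicles = geometry$muscles,
                                   instrumented = seq_along(geometry$discs),
                                   calibration = default_calibration(),
                                   balance_tol = 0.5) {
  if (length(fascicles) == 0) stop("fascicle set is empty", call. = FALSE)
  pcsa <- vapply(fascicles, `[[`, 0, "pcsa")
  n_m <- length(fascicles)
  M_ext <- external_disc_moments(geometry, loadcase)
  arms <- muscle_moment_arms(geometry, fascicles)
  # The cranial boundary (neck/head support at T1) carries a horizontal
  # reaction; it enters the free-body balance as two signed auxiliary
  # variables (split +/- for the NNLS), effectively cost-free.
  p_t1 <- geometry$vertebrae[[1]]$centroid
  r_scale <- 1e4  # N of reaction per unit auxiliary variable
  # stack coronal (My) and sagittal (Mx) balance rows for instrumented discs
  rows <- NULL; b <- NULL
  for (j in instrumented) {
    cj <- geometry$discs[[j]]$center
    arm_rx <- crossprod3(p_t1 - cj, c(1, 0, 0)) * r_scale
    arm_ry <- crossprod3(p_t1 - cj, c(0, 1, 0)) * r_scale
    for (comp in 1:2) {  # Mx, My
      rows <- rbind(rows, c(arms[j, , comp] * pcsa,
                            arm_rx[comp], -arm_rx[comp],
                            arm_ry[comp], -arm_ry[comp]))
      b <- c(b, -M_ext[j, comp])
    }
  }
  cap <- c(rep(calibration$sigma_max, n_m), rep(Inf, 4))
  sol <- solve_muscle_qp(rows, b, cap)
  f_opt <- sol$g[seq_len(n_m)] * pcsa
  f_tot <- f_opt + calibration$tone * pcsa
  reaction <- c(x = (sol$g[n_m + 1] - sol$g[n_m + 2]) * r_scale,
                y = (sol$g[n_m + 3] - sol$g[n_m + 4]) * r_scale)
  structure(list(
    fascicles = fascicles, force = f_tot, force_optimized = f_opt,
    stress = sol$g[seq_len(n_m)], t1_reaction = reaction,
    rel_residual = sol$rel_residual,
    converged = sol$rel_residual < balance_tol,
    instrumented = instrumented
  ), class = "muscle_forces")
}

#' @export
print.muscle_forces <- function(x, ...) {
  cat(sprintf("muscle_forces: %d fascicles, total %.1f N, relative moment residual %.2e (%s)\n",
              length(x$fascicles), sum(x$force), x$rel_residual,
              if (x$converged) "balanced" else "NOT balanced"))
  invisible(x)
}
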