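# Small geometric helpers shared across modules. Units: mm, N, MPa, degrees
# at the interface (radians internally); global frame X coronal (+ = patient
# right), Y sagittal (+ = anterior), Z vertical (+ = cranial).

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

skew <- function(v) {
  matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
}

unit3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < .Machine$double.eps) stop("cannot normalize a zero vector", call. = FALSE)
  v / n
}

rot_z <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(ca, sa, 0, -sa, ca, 0, 0, 0, 1), 3, 3)
}

# Rodrigues rotation from a rotation vector (axis * angle, radians).
rot_vec <- function(r) {
  a <- sqrt(sum(r^2))
  if (a < 1e-12) return(diag(3) + skew(r))
  k <- r / a
  K <- skew(k)
  diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
}

# Minimal rotation taking e_z onto unit vector t.
rot_align_z <- function(t) {
  t <- unit3(t)
  ez <- c(0, 0, 1)
  c_ <- sum(ez * t)
  ax <- c(ez[2] * t[3] - ez[3] * t[2], ez[3] * t[1] - ez[1] * t[3],
          ez[1] * t[2] - ez[2] * t[1])
  s <- sqrt(sum(ax^2))
  if (s < 1e-12) {
    if (c_ > 0) return(diag(3))
    return(diag(c(1, -1, -1)))  # antipodal: flip about x
  }
  rot_vec(ax / s * atan2(s, c_))
}

# C1 smooth monotone interpolation between knot values: flat (zero slope) at
# every knot so extrema sit exactly on the knots.
smoothstep_interp <- function(knot_idx, knot_val, at) {
  stopifnot(length(knot_idx) == length(knot_val), !is.unsorted(knot_idx))
  out <- numeric(length(at))
  for (j in seq_along(at)) {
    x <- at[j]
    if (x <= knot_idx[1]) { out[j] <- knot_val[1]; next }
    k <- length(knot_idx)
    if (x >= knot_idx[k]) { out[j] <- knot_val[k]; next }
    i <- findInterval(x, knot_idx)
    u <- (x - knot_idx[i]) / (knot_idx[i + 1] - knot_idx[i])
    w <- (1 - cos(pi * u)) / 2
    out[j] <- knot_val[i] + (knot_val[i + 1] - knot_val[i]) * w
  }
  out
}

linear_interp <- function(knot_idx, knot_val, at) {
  stats::approx(knot_idx, knot_val, xout = at, rule = 2)$y
}
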