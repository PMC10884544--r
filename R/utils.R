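# Geometry helpers shared across the forward model, fitting and cohort code.

DEG <- pi / 180

vec_norm <- function(v) sqrt(sum(v^2))

assert_unit <- function(v, name, tol = 1e-8) {
  if (length(v) != 3L || !is.numeric(v)) {
    abort(sprintf("`%s` must be a numeric vector of length 3.", name))
  }
  if (abs(vec_norm(v) - 1) > tol) {
    abort(sprintf("`%s` must be a unit vector (|%s| = 1 within %g).",
                  name, name, tol))
  }
  invisible(v)
}

#' Folded angle between two axes
#'
#' Angle between two directions treated as axes (antipodally symmetric), i.e.
#' `acos(|u . v|)` in degrees, always in \[0, 90\]. Fibres have no polarity,
#' so every orientation-dependent quantity in the package uses this folded
#' angle.
#'
#' @param u,v Unit 3-vectors.
#' @return Angle in degrees in \[0, 90\].
#' @export
#' @examples
#' fold_angle(c(0, 0, 1), c(0, 0, -1)) # 0: antipodal fold
#' fold_angle(c(1, 0, 0), c(0, 0, 1))  # 90
fold_angle <- function(u, v) {
  if (vec_norm(u) == 0 || vec_norm(v) == 0) {
    abort("Cannot compute an angle with a zero-length vector.")
  }
  u <- u / vec_norm(u)
  v <- v / vec_norm(v)
  acos(min(1, abs(sum(u * v)))) / DEG
}

# Rodrigues rotation matrix about a unit axis, angle in degrees.
rotation_about_axis <- function(axis, angle_deg) {
  assert_unit(axis, "axis")
  a <- angle_deg * DEG
  K <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
}

# Orthonormal frame (u, v) completing a unit vector n.
complete_frame <- function(n) {
  ref <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- ref - sum(ref * n) * n
  u <- u / vec_norm(u)
  v <- c(n[2] * u[3] - n[3] * u[2],
         n[3] * u[1] - n[1] * u[3],
         n[1] * u[2] - n[2] * u[1])
  cbind(u = u, v = v)
}

#' Fractional anisotropy from an eigenvalue triple
#'
#' Standard FA formula `sqrt(3/2) * ||lambda - mean|| / ||lambda||`. Returns 0
#' for an all-zero triple (isotropic degenerate case).
#'
#' @param lambda Numeric length-3 vector of tensor eigenvalues.
#' @return FA in \[0, 1\] for non-negative eigenvalues.
#' @export
fa_from_eigenvalues <- function(lambda) {
  stopifnot(length(lambda) == 3L)
  ss <- sum(lambda^2)
  if (ss == 0) return(0)
  lbar <- mean(lambda)
  min(1, sqrt(1.5) * sqrt(sum((lambda - lbar)^2)) / sqrt(ss))
}

#' The magic angle
#'
#' Root of `3 cos^2(theta) - 1` in \[0, 90\] degrees: `acos(1/sqrt(3))`, the
#' angle at which the dipolar relaxation factor `(3 cos^2(theta) - 1)^2`
#' vanishes.
#'
#' @return Angle in degrees (about 54.7).
#' @export
magic_angle <- function() acos(1 / sqrt(3)) / DEG
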