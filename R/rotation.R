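# 3-D rotation algebra used throughout the package.
#
# Conventions (fixed package-wide):
#   * Right-handed space frame: x forward (reference gaze direction),
#     y left, z up, so x cross y = z.
#   * All rotations are active: an orientation matrix maps reference-condition
#     vectors onto current vectors.
#   * Angles are in degrees at every exported interface; radians are used
#     internally only.
#   * "Torsion" is rotation about the forward (+x) axis; positive torsion is
#     counterclockwise by the right-hand rule, seen from behind the head.

DEG <- pi / 180

.deg2rad <- function(x) x * DEG
.rad2deg <- function(x) x / DEG

#' Validate a rotation matrix
#'
#' Checks that `R` is a 3 x 3 real matrix that is orthonormal with
#' determinant +1 (a proper rotation) within `tol` in Frobenius norm.
#'
#' @param R object to check.
#' @param tol numeric tolerance (Frobenius norm of `R R^T - I` and
#'   deviation of `det(R)` from 1).
#' @return `TRUE` or `FALSE`.
#' @export
is_rotation <- function(R, tol = 1e-9) {
  if (!is.matrix(R) || !is.numeric(R) || !all(dim(R) == c(3L, 3L))) {
    return(FALSE)
  }
  if (anyNA(R)) return(FALSE)
  d <- R %*% t(R) - diag(3)
  sqrt(sum(d^2)) <= tol && abs(det(R) - 1) <= tol
}

.stop_if_not_rotation <- function(R, arg = "R") {
  if (!is_rotation(R)) {
    stop(sprintf("'%s' is not a proper rotation matrix (orthonormal, det +1)",
                 arg), call. = FALSE)
  }
  invisible(R)
}

#' Rotation about an arbitrary axis (Rodrigues formula)
#'
#' Builds the active right-handed rotation by `tau_deg` degrees about the
#' unit axis `u`.
#'
#' @param u numeric length-3 unit vector (checked to 1e-9).
#' @param tau_deg rotation magnitude in degrees.
#' @return 3 x 3 rotation matrix.
#' @examples
#' rot_about_axis(c(0, 0, 1), 90) %*% c(1, 0, 0)  # -> (0, 1, 0)
#' @export
rot_about_axis <- function(u, tau_deg) {
  u <- as.numeric(u)
  if (length(u) != 3L || anyNA(u)) {
    stop("axis 'u' must be a numeric 3-vector", call. = FALSE)
  }
  if (abs(sqrt(sum(u^2)) - 1) > 1e-9) {
    stop("axis 'u' must be a unit vector (|u| = 1 within 1e-9)",
         call. = FALSE)
  }
  tau <- .deg2rad(tau_deg)
  ct <- cos(tau)
  st <- sin(tau)
  # K is the cross-product (skew) matrix of u; R = I + sin K + (1-cos) K^2
  K <- matrix(c(0, u[3], -u[2],
                -u[3], 0, u[1],
                u[2], -u[1], 0), 3, 3)
  diag(3) + st * K + (1 - ct) * (K %*% K)
}

#' Axis-angle decomposition of a rotation
#'
#' Recovers the unit axis and magnitude (degrees, in `[0, 180]`) such that
#' [rot_about_axis()] reconstructs `R`. Degenerate cases are resolved
#' deterministically: the identity returns axis `c(0, 0, 1)` with zero
#' magnitude, and near 180 degrees the axis sign is fixed so that its
#' largest-magnitude component is positive.
#'
#' @param R 3 x 3 rotation matrix.
#' @return list with `u` (unit 3-vector) and `tau` (degrees).
#' @export
axis_angle_of <- function(R) {
  .stop_if_not_rotation(R)
  tr <- sum(diag(R))
  ct <- (tr - 1) / 2
  ct <- min(1, max(-1, ct))
  tau <- acos(ct)
  if (tau < 1e-9) {
    return(list(u = c(0, 0, 1), tau = 0))
  }
  if (pi - tau < 1e-4) {
    # Near 180 deg the antisymmetric part vanishes; the symmetric part of R
    # is cos(tau) I + (1 - cos(tau)) u u^T, and 1 - cos(tau) ~ 2 is
    # well-conditioned here, so extract the axis from it exactly.
    S <- (R + t(R)) / 2 - ct * diag(3)
    d <- pmax(diag(S), 0)
    k <- which.max(d)
    u <- S[, k] / sqrt(d[k] * (1 - ct))
    u <- u / sqrt(sum(u^2))
    sa <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) / 2
    st <- sqrt(sum(sa^2))
    tau <- atan2(st, ct)
    if (st > 1e-12) {
      if (sum(sa * u) < 0) u <- -u
    } else {
      # tau = 180 deg exactly: both axis signs are valid; fix the sign so
      # the largest-magnitude component is positive
      j <- which.max(abs(u))
      if (u[j] < 0) u <- -u
    }
    return(list(u = u, tau = .rad2deg(tau)))
  }
  ax <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
  st <- sqrt(sum(ax^2)) / 2
  tau <- atan2(st, ct)
  u <- ax / (2 * st)
  list(u = u / sqrt(sum(u^2)), tau = .rad2deg(tau))
}

#' Rotation vector of a rotation
#'
#' Returns the rotation vector `u * tau` in degrees. Component 1 (x) is the
#' torsional coordinate (rotation about the forward axis), component 2 (y)
#' the vertical-rotation coordinate, component 3 (z) the horizontal-rotation
#' coordinate. An eye-in-head orientation obeys Listing's law iff the x
#' component is zero.
#'
#' @param R 3 x 3 rotation matrix.
#' @return numeric 3-vector, degrees.
#' @export
rotvec_of <- function(R) {
  aa <- axis_angle_of(R)
  aa$u * aa$tau
}

#' Rotation from a rotation vector
#'
#' Inverse of [rotvec_of()]: `r` is an axis-times-angle vector in degrees.
#'
#' @param r numeric 3-vector, degrees.
#' @return 3 x 3 rotation matrix.
#' @export
rotation_from_rotvec <- function(r) {
  r <- as.numeric(r)
  if (length(r) != 3L || anyNA(r)) {
    stop("'r' must be a numeric 3-vector", call. = FALSE)
  }
  tau <- sqrt(sum(r^2))
  if (tau == 0) return(diag(3))
  rot_about_axis(r / tau, tau)
}

#' Compose rotations
#'
#' Matrix product of its arguments; the rightmost rotation is applied first,
#' matching the gaze composition `G = H %*% E` (head applied to the
#' eye-in-head result).
#'
#' @param ... 3 x 3 rotation matrices, outermost first.
#' @return 3 x 3 rotation matrix.
#' @export
compose <- function(...) {
  Rs <- list(...)
  out <- diag(3)
  for (R in Rs) out <- out %*% R
  out
}

#' Invert a rotation
#'
#' @param R 3 x 3 rotation matrix.
#' @return the transpose of `R` (its inverse).
#' @export
invert <- function(R) t(R)

#' Project a near-rotation matrix onto the rotation group
#'
#' Returns the nearest orthonormal matrix (Frobenius sense) with det +1,
#' via the SVD polar factor. Useful to clean accumulated round-off; an input
#' already orthonormal within 1e-9 is returned with only the projection
#' applied (no-op up to round-off).
#'
#' @param R 3 x 3 numeric matrix close to a rotation.
#' @return 3 x 3 rotation matrix.
#' @export
orthonormalize <- function(R) {
  if (!is.matrix(R) || !all(dim(R) == c(3L, 3L))) {
    stop("'R' must be a 3 x 3 matrix", call. = FALSE)
  }
  s <- svd(R)
  D <- diag(c(1, 1, sign(det(s$u %*% t(s$v)))))
  s$u %*% D %*% t(s$v)
}

#' Fick rotation matrix
#'
#' Composes successive rotations about the body-fixed vertical axis
#' (`theta`), the interim horizontal axis (`phi`), and the torsional
#' (forward) axis (`psi`), in that order:
#' `Rz(theta) %*% Ry(phi) %*% Rx(psi)`. With `psi = 0` the bottom row is
#' `(-sin phi, 0, cos phi)`.
#'
#' @param theta rotation about the space-vertical axis, degrees.
#' @param phi rotation about the interim horizontal axis, degrees
#'   (`|phi| < 90`; 90 is the gimbal-lock singularity).
#' @param psi torsional rotation, degrees.
#' @return 3 x 3 rotation matrix.
#' @export
fick_matrix <- function(theta, phi, psi = 0) {
  if (abs(phi) >= 90) {
    stop("gimbal lock: |phi| must be < 90 degrees", call. = FALSE)
  }
  rot_about_axis(c(0, 0, 1), theta) %*%
    rot_about_axis(c(0, 1, 0), phi) %*%
    rot_about_axis(c(1, 0, 0), psi)
}

#' Fick angles of a rotation
#'
#' Inverse of [fick_matrix()]. `psi` is the Fick torsion of the orientation:
#' a head orientation satisfies the Fick constraint iff `psi = 0`.
#'
#' @param R 3 x 3 rotation matrix with `|phi| < 90` degrees.
#' @return list with `theta`, `phi`, `psi` in degrees.
#' @export
fick_angles_of <- function(R) {
  .stop_if_not_rotation(R)
  sphi <- -R[3, 1]
  if (abs(sphi) >= 1 - 1e-12) {
    stop("gimbal lock: |phi| = 90 degrees, Fick angles undefined",
         call. = FALSE)
  }
  phi <- asin(sphi)
  theta <- atan2(R[2, 1], R[1, 1])
  psi <- atan2(R[3, 2], R[3, 3])
  list(theta = .rad2deg(theta), phi = .rad2deg(phi), psi = .rad2deg(psi))
}

#' Torsion metrics
#'
#' `listing_torsion()` is the x (forward-axis) component of the rotation
#' vector of an eye-in-head orientation; it is zero iff the rotation axis
#' lies in Listing's plane. `fick_torsion()` is the Fick angle `psi` of a
#' head orientation; it is zero iff the orientation lies on the zero-torsion
#' Fick surface.
#'
#' @param R 3 x 3 rotation matrix.
#' @return torsion in degrees.
#' @export
listing_torsion <- function(R) rotvec_of(R)[1]

#' @rdname listing_torsion
#' @export
fick_torsion <- function(R) fick_angles_of(R)$psi
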