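# Conversions among screen targets, unit direction vectors, 2-D angular
# positions, and retinal error.
#
# Units: angles in degrees, screen offsets and eye-screen distance in cm.
# The screen is flat, orthogonal to the reference gaze direction (+x), at
# distance t from the eye; its horizontal axis is +y (left), vertical +z (up).

.unit <- function(v) v / sqrt(sum(v^2))

.check_unit <- function(v, arg = "v") {
  v <- as.numeric(v)
  if (length(v) != 3L || anyNA(v)) {
    stop(sprintf("'%s' must be a numeric 3-vector", arg), call. = FALSE)
  }
  if (abs(sqrt(sum(v^2)) - 1) > 1e-9) {
    stop(sprintf("'%s' must be a unit vector", arg), call. = FALSE)
  }
  v
}

#' Direction vector from 2-D angular position
#'
#' Maps azimuth `gamma` (positive toward +y) and elevation `eta` (positive
#' toward +z, measured from the horizontal plane) to a unit direction:
#' `c(cos(eta) cos(gamma), cos(eta) sin(gamma), sin(eta))`.
#'
#' @param gamma horizontal azimuth, degrees, `|gamma| < 90`.
#' @param eta vertical elevation, degrees, `|eta| < 90`.
#' @return unit 3-vector.
#' @export
dir_from_angles <- function(gamma, eta) {
  if (abs(gamma) >= 90 || abs(eta) >= 90) {
    stop("angular position out of the front hemisphere (|angle| < 90 deg)",
         call. = FALSE)
  }
  g <- .deg2rad(gamma)
  e <- .deg2rad(eta)
  c(cos(e) * cos(g), cos(e) * sin(g), sin(e))
}

#' 2-D angular position of a direction vector
#'
#' Inverse of [dir_from_angles()]; requires the direction to lie in the
#' front hemisphere (`v[1] > 0`).
#'
#' @param v unit 3-vector with positive x component.
#' @return list with `gamma` and `eta`, degrees.
#' @export
angles_from_dir <- function(v) {
  v <- .check_unit(v)
  if (v[1] <= 0) {
    stop("direction outside the front hemisphere (x component must be > 0)",
         call. = FALSE)
  }
  list(gamma = .rad2deg(atan2(v[2], v[1])),
       eta = .rad2deg(asin(min(1, max(-1, v[3])))))
}

#' Gaze direction toward a screen target
#'
#' A target at horizontal offset `a` (cm, positive toward +y) and vertical
#' offset `b` (cm, positive up) on a screen at distance `t` (cm) subtends
#' the unit direction proportional to `c(t, a, b)`.
#'
#' @param a horizontal screen offset, cm.
#' @param b vertical screen offset, cm.
#' @param t eye-to-screen distance, cm (> 0).
#' @return unit 3-vector.
#' @export
gaze_from_screen_target <- function(a, b, t = 100) {
  if (!is.finite(t) || t <= 0) stop("screen distance 't' must be > 0",
                                    call. = FALSE)
  .unit(c(t, a, b))
}

#' Screen intersection of a gaze direction
#'
#' Returns the screen offsets `(a, b)` in cm where the gaze ray pierces the
#' screen plane at distance `t`. The default is the central projection
#' `a = t v_y / v_x`, `b = t v_z / v_x`, the exact inverse of
#' [gaze_from_screen_target()]. `projection = "orthographic"` instead scales
#' the raw components (`a = t v_y`, `b = t v_z`), a small-angle
#' approximation that is not the inverse of the forward map.
#'
#' @param v unit gaze direction, front hemisphere.
#' @param t eye-to-screen distance, cm.
#' @param projection `"central"` (default) or `"orthographic"`.
#' @return list with `a` and `b`, cm.
#' @export
screen_target_from_gaze <- function(v, t = 100,
                                    projection = c("central",
                                                   "orthographic")) {
  v <- .check_unit(v)
  projection <- match.arg(projection)
  if (v[1] <= 0) {
    stop("gaze does not intersect the screen (x component must be > 0)",
         call. = FALSE)
  }
  if (projection == "central") {
    list(a = t * v[2] / v[1], b = t * v[3] / v[1])
  } else {
    list(a = t * v[2], b = t * v[3])
  }
}

#' Retinal error vector of a target
#'
#' Expresses the desired gaze direction `g_d` in the coordinates of the
#' current eye (gaze orientation `G_i`): `g_RE = G_i^{-1} %*% g_d`. The
#' result equals `c(1, 0, 0)` iff the target is already foveated.
#'
#' @param G_i current gaze (eye-in-space) orientation, 3 x 3 rotation.
#' @param g_d desired gaze direction, unit 3-vector.
#' @return unit 3-vector in retinal (eye-fixed) coordinates.
#' @export
retinal_error_vector <- function(G_i, g_d) {
  .stop_if_not_rotation(G_i, "G_i")
  g_d <- .check_unit(g_d, "g_d")
  as.numeric(invert(G_i) %*% g_d)
}

#' Desired gaze direction from a retinal error
#'
#' Inverse of [retinal_error_vector()]: rotates an eye-fixed retinal error
#' back into space coordinates, `g_d = G_i %*% g_RE`. This is the input mode
#' in which the same retinal stimulation is imposed from different initial
#' orientations.
#'
#' @param G_i current gaze orientation, 3 x 3 rotation.
#' @param g_RE retinal error direction, unit 3-vector.
#' @return unit 3-vector in space coordinates.
#' @export
desired_gaze_from_retinal_error <- function(G_i, g_RE) {
  .stop_if_not_rotation(G_i, "G_i")
  g_RE <- .check_unit(g_RE, "g_RE")
  as.numeric(G_i %*% g_RE)
}

#' Spherical angles of a retinal error vector
#'
#' Reports a retinal error direction as a polar angle from the retinal z
#' axis and an azimuth within the transverse plane. The azimuth uses the
#' two-argument arctangent so its sign is preserved. This convention
#' (polar from z) differs from the elevation-from-horizontal convention of
#' [angles_from_dir()] and is provided for reporting only.
#'
#' @param g_RE unit 3-vector.
#' @return list with `polar` and `azimuth`, degrees.
#' @export
retinal_error_angles <- function(g_RE) {
  g_RE <- .check_unit(g_RE, "g_RE")
  cz <- min(1, max(-1, g_RE[3]))
  if (1 - abs(cz) < 1e-12) {
    stop("retinal error at the polar axis: azimuth undefined", call. = FALSE)
  }
  list(polar = .rad2deg(acos(cz)),
       azimuth = .rad2deg(atan2(g_RE[1], g_RE[2])))
}

#' Angular eccentricity between two directions
#'
#' The angle in degrees between two unit vectors; used for gaze accuracy
#' (retinal eccentricity of the target image from the fovea).
#'
#' @param v1,v2 unit 3-vectors.
#' @return angle in degrees.
#' @export
angle_between <- function(v1, v2) {
  v1 <- .check_unit(v1, "v1")
  v2 <- .check_unit(v2, "v2")
  # atan2 form is accurate for both tiny and near-180 deg separations
  .rad2deg(atan2(sqrt(sum(crossprod_vec(v1, v2)^2)), sum(v1 * v2)))
}

# plain cross product (kept internal)
crossprod_vec <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
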