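# Static kinematic model of a head-free gaze shift.
#
# The gaze shift is decomposed into three sequenced motor mechanisms:
#   stage 1  saccade           eye rotates in head by Re, head fixed
#   stage 2  eye-carrying head rotation Rh, eye-in-head fixed (foveates target)
#   stage 3  gaze-stabilized head rotation Rw with compensatory VOR Rv
#
# Desired orientations:  E_d = Rv Re E_i,  H_d = Rw Rh H_i,
#                        G_d = Rw Rh H_i Rv Re E_i  (= H_d E_d).
#
# The solver works backwards from the constraints: the desired head
# orientation is the zero-torsion Fick orientation pointing at the desired
# 2-D head position (an alpha/beta interpolation between initial head and
# desired gaze angles); the desired eye-in-head orientation is the Listing
# orientation pointing at the remaining eye direction; the single head
# rotation Rt = H_d H_i^-1 is split about its fixed axis into a
# gaze-contributing part Rh (fraction delta) and a VOR-cancelled part Rw;
# the ideal VOR Rv follows from 3-D gaze stability, and the saccade Re
# pre-compensates it.

#' Eye-head state
#'
#' Bundles an eye-in-head orientation `E` and a head-in-space orientation
#' `H`. The gaze (eye-in-space) orientation is always the derived product
#' `G = H %*% E`; it is recomputed on demand and never stored.
#'
#' @param E eye-in-head orientation, 3 x 3 rotation matrix.
#' @param H head-in-space orientation, 3 x 3 rotation matrix.
#' @return object of class `"eye_head_state"`.
#' @export
eye_head_state <- function(E = diag(3), H = diag(3)) {
  .stop_if_not_rotation(E, "E")
  .stop_if_not_rotation(H, "H")
  structure(list(E = E, H = H), class = "eye_head_state")
}

#' Gaze orientation of a state
#'
#' @param state an `eye_head_state`.
#' @return 3 x 3 rotation matrix `H %*% E`.
#' @export
gaze_of <- function(state) {
  stopifnot(inherits(state, "eye_head_state"))
  state$H %*% state$E
}

#' @export
print.eye_head_state <- function(x, ...) {
  ae <- axis_angle_of(x$E)
  ah <- axis_angle_of(x$H)
  g <- gaze_of(x) %*% c(1, 0, 0)
  ga <- angles_from_dir(as.numeric(g))
  cat("Eye-head state\n")
  cat(sprintf("  eye-in-head : %.3f deg about (%.3f, %.3f, %.3f)\n",
              ae$tau, ae$u[1], ae$u[2], ae$u[3]))
  cat(sprintf("  head-in-space: %.3f deg about (%.3f, %.3f, %.3f)\n",
              ah$tau, ah$u[1], ah$u[2], ah$u[3]))
  cat(sprintf("  gaze direction: azimuth %.3f deg, elevation %.3f deg\n",
              ga$gamma, ga$eta))
  invisible(x)
}

#' Coordination parameters of the gaze-shift planner
#'
#' @param alpha head horizontal-contribution weight in `[0, 1]`: the
#'   fraction of the horizontal gap between initial head direction and
#'   desired gaze direction that the head closes.
#' @param beta head vertical-contribution weight in `[0, 1]`.
#' @param delta head-rotation phase split in `[0, 1]`: fraction of the total
#'   head rotation executed while the head still contributes to the gaze
#'   shift; the remaining `1 - delta` is cancelled by the VOR.
#' @param t eye-to-screen distance in cm, used when targets are given as
#'   screen offsets.
#' @return object of class `"gaze_params"`.
#' @details The interpolation weights are naturally open-interval parameters;
#'   the boundary values 0 and 1 are accepted and handled as exact limits
#'   (e.g. `alpha = beta = 0` keeps the head fixed, `delta = 1` suppresses
#'   the VOR stage).
#' @export
gaze_params <- function(alpha = 0.5, beta = 0.5, delta = 0.5, t = 100) {
  for (nm in c("alpha", "beta", "delta")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      stop(sprintf("'%s' must be a single number in [0, 1]", nm),
           call. = FALSE)
    }
  }
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t <= 0) {
    stop("'t' must be a single positive number (cm)", call. = FALSE)
  }
  structure(list(alpha = alpha, beta = beta, delta = delta, t = t),
            class = "gaze_params")
}

#' Desired 2-D head position
#'
#' Componentwise interpolation between the initial head direction angles and
#' the desired gaze direction angles:
#' `b_d = b_i + (alpha, beta) * (c_d - b_i)`.
#'
#' @param b_i initial head angles, list/vector with `gamma`, `eta` (deg).
#' @param c_d desired gaze angles, same form.
#' @param alpha,beta interpolation weights in `[0, 1]`.
#' @return list with `gamma`, `eta` (deg).
#' @export
desired_head_angles <- function(b_i, c_d, alpha, beta) {
  b_i <- unlist(b_i)[c("gamma", "eta")]
  c_d <- unlist(c_d)[c("gamma", "eta")]
  list(gamma = unname(b_i["gamma"] + alpha * (c_d["gamma"] - b_i["gamma"])),
       eta = unname(b_i["eta"] + beta * (c_d["eta"] - b_i["eta"])))
}

#' Zero-torsion Fick orientation pointing along a direction
#'
#' The unique rotation with zero Fick torsion whose action on the reference
#' direction `c(1, 0, 0)` yields `h_d`: `phi = asin(-h_z)`,
#' `theta = atan2(h_y, h_x)`, `psi = 0`.
#'
#' @param h_d unit direction in the front hemisphere.
#' @return 3 x 3 rotation matrix.
#' @export
fick_orientation_from_dir <- function(h_d) {
  h_d <- .check_unit(h_d, "h_d")
  if (abs(h_d[3]) >= 1 - 1e-12) {
    stop("gimbal lock: direction along the vertical axis", call. = FALSE)
  }
  phi <- asin(-h_d[3])
  theta <- atan2(h_d[2], h_d[1])
  fick_matrix(.rad2deg(theta), .rad2deg(phi), 0)
}

#' Listing orientation pointing along a direction
#'
#' The unique rotation about an axis in Listing's plane (zero torsional
#' rotation-vector component) whose action on `c(1, 0, 0)` yields `e_d`:
#' magnitude `tau = acos(e_x)` about axis
#' `(0, -e_z, e_y) / sin(tau)`.
#'
#' @param e_d unit direction with `e_d[1] > -1`.
#' @return 3 x 3 rotation matrix.
#' @export
listing_orientation_from_dir <- function(e_d) {
  e_d <- .check_unit(e_d, "e_d")
  s <- sqrt(e_d[2]^2 + e_d[3]^2)
  if (s < 1e-15) {
    if (e_d[1] > 0) return(diag(3))
    stop("direction 180 degrees from primary position: Listing orientation undefined",
         call. = FALSE)
  }
  # atan2 keeps tau well-conditioned near primary position (acos is not)
  tau <- atan2(s, e_d[1])
  u <- c(0, -e_d[3], e_d[2]) / s
  rot_about_axis(u / sqrt(sum(u^2)), .rad2deg(tau))
}

#' Split a rotation about its fixed axis
#'
#' Decomposes `Rt` into two coaxial rotations `Rh` (magnitude
#' `delta * tau`) and `Rw` (magnitude `(1 - delta) * tau`) with
#' `Rw %*% Rh == Rt`.
#'
#' @param Rt 3 x 3 rotation matrix.
#' @param delta fraction in `[0, 1]`.
#' @return list with `Rh` and `Rw`.
#' @export
split_rotation <- function(Rt, delta) {
  .stop_if_not_rotation(Rt, "Rt")
  if (delta < 0 || delta > 1) stop("'delta' must be in [0, 1]", call. = FALSE)
  aa <- axis_angle_of(Rt)
  list(Rh = rot_about_axis(aa$u, delta * aa$tau),
       Rw = rot_about_axis(aa$u, (1 - delta) * aa$tau))
}

#' Ideal VOR rotation
#'
#' The compensatory eye-in-head rotation that keeps the full 3-D gaze
#' orientation constant while the head executes its second-phase rotation
#' `Rw`: `Rv = H_i^-1 Rh^-1 Rw^-1 Rh H_i`, so that
#' `Rw Rh H_i Rv = Rh H_i`.
#'
#' @param H_i initial head orientation.
#' @param Rh first-phase head rotation.
#' @param Rw second-phase head rotation.
#' @return 3 x 3 rotation matrix.
#' @export
vor_rotation <- function(H_i, Rh, Rw) {
  invert(H_i) %*% invert(Rh) %*% invert(Rw) %*% Rh %*% H_i
}

.resolve_target <- function(state_i, target, t) {
  if (is.list(target) && !is.null(target$a) && !is.null(target$b)) {
    tt <- if (!is.null(target$t)) target$t else t
    g_d <- gaze_from_screen_target(target$a, target$b, tt)
    mode <- "screen"
  } else if (is.list(target) && !is.null(target$gamma) &&
             !is.null(target$eta)) {
    g_d <- dir_from_angles(target$gamma, target$eta)
    mode <- "angles"
  } else if (is.list(target) && !is.null(target$retinal_error)) {
    g_RE <- .unit(as.numeric(target$retinal_error))
    g_d <- desired_gaze_from_retinal_error(gaze_of(state_i), g_RE)
    mode <- "retinal_error"
  } else if (is.numeric(target) && length(target) == 3L) {
    g_d <- .unit(as.numeric(target))
    mode <- "direction"
  } else {
    stop(paste("'target' must be list(a=, b=[, t=]) screen offsets in cm,",
               "list(gamma=, eta=) angles in deg,",
               "list(retinal_error=) an eye-fixed direction,",
               "or a unit 3-vector in space coordinates"), call. = FALSE)
  }
  list(g_d = g_d, mode = mode)
}

#' Plan a 3-D head-free gaze shift
#'
#' Solves the static kinematic model: from the initial eye-head state and a
#' target it computes the saccade `Re`, the two-phase head rotation
#' `Rh`, `Rw` (total `Rt = Rw %*% Rh`), the predicted VOR `Rv`, and the
#' desired orientations `E_d` (in Listing's plane), `H_d` (zero Fick
#' torsion) and `G_d` (foveating the target).
#'
#' @param state_i initial [eye_head_state()]. The initial orientations need
#'   not satisfy the Listing/Fick constraints; the plan drives the final
#'   orientations into them.
#' @param target target specification: `list(a=, b=)` screen offsets in cm
#'   (optionally `t=`), `list(gamma=, eta=)` gaze angles in degrees,
#'   `list(retinal_error=)` an eye-fixed direction vector, or a unit
#'   3-vector in space coordinates.
#' @param params a [gaze_params()] object.
#' @return object of class `"gaze_plan"`: a list with the stage rotations
#'   `Re`, `Rh`, `Rw`, `Rt`, `Rv`, `Ra`, desired orientations `E_d`, `H_d`,
#'   `G_d`, desired gaze direction `g_d`, displacement commands `dE`, `dH`
#'   (rotation-vector differences, degrees), the initial state, the resolved
#'   target and the parameters.
#' @examples
#' p <- plan_gaze_shift(eye_head_state(), list(gamma = 60, eta = 0),
#'                      gaze_params(0.5, 0.5, 0.5))
#' summary(p)
#' @export
plan_gaze_shift <- function(state_i = eye_head_state(),
                            target,
                            params = gaze_params()) {
  stopifnot(inherits(state_i, "eye_head_state"))
  if (!inherits(params, "gaze_params")) {
    stop("'params' must be a gaze_params object", call. = FALSE)
  }
  tg <- .resolve_target(state_i, target, params$t)
  g_d <- tg$g_d
  if (g_d[1] <= 0) {
    stop("target unreachable: desired gaze direction leaves the front hemisphere",
         call. = FALSE)
  }

  # desired 2-D head position from alpha/beta interpolation
  c_d <- angles_from_dir(g_d)
  h_i <- as.numeric(state_i$H %*% c(1, 0, 0))
  if (h_i[1] <= 0) {
    stop("initial head direction outside the front hemisphere", call. = FALSE)
  }
  b_i <- angles_from_dir(h_i)
  b_d <- desired_head_angles(b_i, c_d, params$alpha, params$beta)
  if (abs(b_d$gamma) >= 90 || abs(b_d$eta) >= 90) {
    stop("target unreachable: desired head direction leaves the front hemisphere",
         call. = FALSE)
  }
  h_d <- dir_from_angles(b_d$gamma, b_d$eta)

  # head: zero-torsion Fick orientation, single fixed-axis rotation, split
  H_d <- fick_orientation_from_dir(h_d)
  Rt <- H_d %*% invert(state_i$H)
  sp <- split_rotation(Rt, params$delta)
  Rh <- sp$Rh
  Rw <- sp$Rw

  # eye: remaining direction in desired head coordinates, Listing orientation
  e_d <- as.numeric(invert(H_d) %*% g_d)
  if (e_d[1] <= 0) {
    stop("target unreachable: desired eye-in-head direction leaves the front hemisphere",
         call. = FALSE)
  }
  E_d <- listing_orientation_from_dir(e_d)
  Ra <- E_d %*% invert(state_i$E)

  # predicted VOR, saccade pre-compensating it
  Rv <- vor_rotation(state_i$H, Rh, Rw)
  Re <- invert(Rv) %*% Ra

  G_d <- H_d %*% E_d
  dE <- rotvec_of(Re %*% state_i$E) - rotvec_of(state_i$E)
  dH <- rotvec_of(H_d) - rotvec_of(state_i$H)

  structure(list(
    Re = Re, Rh = Rh, Rw = Rw, Rt = Rt, Rv = Rv, Ra = Ra,
    E_d = E_d, H_d = H_d, G_d = G_d,
    g_d = g_d, c_d = c_d, b_d = b_d,
    dE = dE, dH = dH,
    state_i = state_i, target = tg, params = params
  ), class = "gaze_plan")
}

#' Displacement commands of a plan
#'
#' Rotation-vector differences between post-saccadic and initial eye
#' orientation (`dE`) and between desired and initial head orientation
#' (`dH`), in degrees. These are derived views of the authoritative stage
#' rotation matrices; they are the zero vector iff no movement is required.
#'
#' @param plan a `gaze_plan`.
#' @return list with `dE` and `dH`, numeric 3-vectors (deg).
#' @export
displacement_commands <- function(plan) {
  stopifnot(inherits(plan, "gaze_plan"))
  list(dE = plan$dE, dH = plan$dH)
}

#' Final state of a plan
#'
#' @param plan a `gaze_plan`.
#' @return [eye_head_state()] with the desired orientations.
#' @export
final_state <- function(plan) {
  stopifnot(inherits(plan, "gaze_plan"))
  eye_head_state(plan$E_d, plan$H_d)
}

#' @export
print.gaze_plan <- function(x, ...) {
  a_e <- axis_angle_of(x$Re)
  a_t <- axis_angle_of(x$Rt)
  a_v <- axis_angle_of(x$Rv)
  cat("Planned 3-D head-free gaze shift\n")
  cat(sprintf("  target gaze : azimuth %8.3f deg, elevation %8.3f deg (%s input)\n",
              x$c_d$gamma, x$c_d$eta, x$target$mode))
  cat(sprintf("  saccade Re  : %8.3f deg\n", a_e$tau))
  cat(sprintf("  head Rt     : %8.3f deg (phase 1: %.3f, phase 2: %.3f)\n",
              a_t$tau, x$params$delta * a_t$tau,
              (1 - x$params$delta) * a_t$tau))
  cat(sprintf("  VOR Rv      : %8.3f deg\n", a_v$tau))
  cat(sprintf("  params      : alpha %.3g, beta %.3g, delta %.3g\n",
              x$params$alpha, x$params$beta, x$params$delta))
  invisible(x)
}

#' Summarize a gaze plan
#'
#' Reports stage rotation magnitudes, displacement commands, and the
#' constraint residuals: gaze pointing error (deg), Listing torsion of the
#' final eye-in-head orientation, and Fick torsion of the final head
#' orientation.
#'
#' @param object a `gaze_plan`.
#' @param ... unused.
#' @return object of class `"summary.gaze_plan"`.
#' @export
summary.gaze_plan <- function(object, ...) {
  res <- residuals(object)
  out <- list(
    target = object$c_d,
    mode = object$target$mode,
    params = object$params,
    magnitudes = c(saccade = axis_angle_of(object$Re)$tau,
                   head_total = axis_angle_of(object$Rt)$tau,
                   head_phase1 = axis_angle_of(object$Rh)$tau,
                   head_phase2 = axis_angle_of(object$Rw)$tau,
                   vor = axis_angle_of(object$Rv)$tau),
    displacement = displacement_commands(object),
    residuals = res
  )
  class(out) <- "summary.gaze_plan"
  out
}

#' @export
print.summary.gaze_plan <- function(x, ...) {
  cat("Gaze-shift plan summary\n")
  cat(sprintf("  target: azimuth %.3f deg, elevation %.3f deg (%s input)\n",
              x$target$gamma, x$target$eta, x$mode))
  cat(sprintf("  params: alpha %.3g, beta %.3g, delta %.3g, t %.3g cm\n",
              x$params$alpha, x$params$beta, x$params$delta, x$params$t))
  cat("  stage magnitudes (deg):\n")
  m <- x$magnitudes
  for (nm in names(m)) cat(sprintf("    %-11s %10.4f\n", nm, m[[nm]]))
  cat("  displacement commands (rotation-vector deg):\n")
  cat(sprintf("    dE (%9.4f, %9.4f, %9.4f)\n",
              x$displacement$dE[1], x$displacement$dE[2],
              x$displacement$dE[3]))
  cat(sprintf("    dH (%9.4f, %9.4f, %9.4f)\n",
              x$displacement$dH[1], x$displacement$dH[2],
              x$displacement$dH[3]))
  cat("  constraint residuals (deg):\n")
  r <- x$residuals
  cat(sprintf("    gaze pointing error %.3e\n    Listing torsion of E_d %.3e\n    Fick torsion of H_d %.3e\n",
              r["gaze_error"], r["listing_torsion"], r["fick_torsion"]))
  invisible(x)
}

#' Constraint residuals of a gaze plan
#'
#' The model is exact, so all three residuals are zero up to round-off:
#' the angular error between the achieved final gaze direction and the
#' target direction, the Listing torsion of the final eye-in-head
#' orientation, and the Fick torsion of the final head orientation
#' (all in degrees).
#'
#' @param object a `gaze_plan`.
#' @param ... unused.
#' @return named numeric vector.
#' @export
residuals.gaze_plan <- function(object, ...) {
  g_final <- .unit(as.numeric(object$G_d %*% c(1, 0, 0)))
  c(gaze_error = angle_between(g_final, object$g_d),
    listing_torsion = listing_torsion(object$E_d),
    fick_torsion = fick_torsion(object$H_d))
}

#' Coefficients of a gaze plan
#'
#' Returns the motor-command view of the plan: the 3-D eye and head
#' displacement commands (rotation-vector components, degrees).
#'
#' @param object a `gaze_plan`.
#' @param ... unused.
#' @return named numeric vector
#'   `(dE_torsional, dE_vertical, dE_horizontal, dH_...)`.
#' @export
coef.gaze_plan <- function(object, ...) {
  c(dE_torsional = object$dE[1], dE_vertical = object$dE[2],
    dE_horizontal = object$dE[3],
    dH_torsional = object$dH[1], dH_vertical = object$dH[2],
    dH_horizontal = object$dH[3])
}

#' Predicted post-shift fixation
#'
#' @param object a `gaze_plan`.
#' @param ... unused.
#' @return list with the final [eye_head_state()], the gaze direction, its
#'   2-D angles (deg) and its screen intersection (cm, at the plan's screen
#'   distance).
#' @export
predict.gaze_plan <- function(object, ...) {
  st <- final_state(object)
  g <- .unit(as.numeric(gaze_of(st) %*% c(1, 0, 0)))
  list(state = st,
       gaze_direction = g,
       gaze_angles = angles_from_dir(g),
       screen = screen_target_from_gaze(g, object$params$t))
}
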