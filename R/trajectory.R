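# Temporal discretization of a gaze plan.
#
# All eye and head motions follow fixed-axis partial rotations, except the
# VOR stage, where the eye-in-head orientation is re-solved each sample from
# the instantaneous head orientation so that the full 3-D gaze orientation
# stays constant ("online" VOR axis). The growth functions only shape the
# time course; they have no effect on any endpoint.

#' Timing profile for trajectory simulation
#'
#' Onsets and durations (ms) of the saccade and the two head-rotation
#' phases. The saccade may overlap head phase 1 but must end no later than
#' phase 2 begins (`saccade_onset + saccade_duration <=
#' head_onset + head_phase1_duration`), so that the ideal-VOR stage is
#' well-defined.
#'
#' @param saccade_onset,saccade_duration saccade timing, ms.
#' @param head_onset head-movement onset, ms.
#' @param head_phase1_duration,head_phase2_duration durations of the
#'   gaze-contributing and VOR-cancelled head phases, ms.
#' @param growth_kind scalar growth function: `"smoothstep"` (default) or
#'   `"linear"`.
#' @return object of class `"timing_profile"`.
#' @export
timing_profile <- function(saccade_onset = 0, saccade_duration = 100,
                           head_onset = 0, head_phase1_duration = 150,
                           head_phase2_duration = 250,
                           growth_kind = "smoothstep") {
  for (nm in c("saccade_duration", "head_phase1_duration",
               "head_phase2_duration")) {
    if (get(nm) <= 0) stop(sprintf("'%s' must be > 0", nm), call. = FALSE)
  }
  if (saccade_onset < 0 || head_onset < 0) {
    stop("onsets must be >= 0", call. = FALSE)
  }
  if (saccade_onset + saccade_duration >
      head_onset + head_phase1_duration) {
    stop(paste("invalid timing: the saccade must end no later than head",
               "phase 2 begins"), call. = FALSE)
  }
  growth(0.5, growth_kind)  # validates the kind
  structure(list(saccade_onset = saccade_onset,
                 saccade_duration = saccade_duration,
                 head_onset = head_onset,
                 head_phase1_duration = head_phase1_duration,
                 head_phase2_duration = head_phase2_duration,
                 growth_kind = growth_kind),
            class = "timing_profile")
}

#' Scalar growth function
#'
#' Monotone map of normalized time `s` in `[0, 1]` to a completed fraction
#' in `[0, 1]` with `growth(0) = 0` and `growth(1) = 1`. The shape is
#' immaterial to every endpoint property of the model.
#'
#' @param s normalized time, in `[0, 1]` (values outside are clamped).
#' @param kind `"smoothstep"` (`3 s^2 - 2 s^3`) or `"linear"`.
#' @return completed fraction in `[0, 1]`.
#' @export
growth <- function(s, kind = "smoothstep") {
  s <- pmin(1, pmax(0, s))
  switch(kind,
         smoothstep = 3 * s^2 - 2 * s^3,
         linear = s,
         stop(sprintf("unknown growth kind '%s'", kind), call. = FALSE))
}

#' Simulate the trajectory of a planned gaze shift
#'
#' Discretizes a [plan_gaze_shift()] result into `n` time samples. The
#' saccade rotates the eye about the fixed saccade axis; the head rotates
#' about the fixed total-rotation axis, covering fraction `delta` of its
#' magnitude in phase 1 and the remainder in phase 2; during phase 2 the
#' eye-in-head orientation is solved as `H(t)^-1 G_d` (ideal VOR), keeping
#' the 3-D gaze orientation constant. The final sample equals the plan's
#' desired condition; the endpoints are independent of the timing profile.
#'
#' @param object a `gaze_plan`.
#' @param nsim,seed present for compatibility with the [stats::simulate()]
#'   generic; the trajectory is deterministic, so they are ignored.
#' @param timing a [timing_profile()].
#' @param n number of uniformly spaced samples over the full span
#'   (default 200).
#' @param ... unused.
#' @return object of class `"gaze_trajectory"`: list with `time` (ms),
#'   `stage` (factor: pre, saccade, head_phase1, head_phase2_vor, done),
#'   lists `E`, `H` of orientation matrices, and the generating `plan` and
#'   `timing`.
#' @export
simulate.gaze_plan <- function(object, nsim = 1, seed = NULL,
                               timing = timing_profile(), n = 200, ...) {
  stopifnot(inherits(object, "gaze_plan"))
  if (!inherits(timing, "timing_profile")) {
    stop("'timing' must be a timing_profile object", call. = FALSE)
  }
  if (n < 2) stop("'n' must be at least 2", call. = FALSE)
  plan <- object
  state_i <- plan$state_i

  aa_t <- axis_angle_of(plan$Rt)
  aa_e <- axis_angle_of(plan$Re)
  delta <- plan$params$delta

  s_on <- timing$saccade_onset
  s_end <- s_on + timing$saccade_duration
  h_on <- timing$head_onset
  p2_on <- h_on + timing$head_phase1_duration
  h_end <- p2_on + timing$head_phase2_duration
  t_end <- max(s_end, h_end)
  times <- seq(0, t_end, length.out = n)

  G_d <- plan$G_d
  kind <- timing$growth_kind

  E_list <- vector("list", n)
  H_list <- vector("list", n)
  stage <- character(n)

  for (k in seq_len(n)) {
    tt <- times[k]
    # head: fixed-axis rotation through the two phases
    if (tt <= h_on) {
      head_tau <- 0
    } else if (tt < p2_on) {
      f <- growth((tt - h_on) / timing$head_phase1_duration, kind)
      head_tau <- delta * aa_t$tau * f
    } else if (tt < h_end) {
      f <- growth((tt - p2_on) / timing$head_phase2_duration, kind)
      head_tau <- aa_t$tau * (delta + (1 - delta) * f)
    } else {
      head_tau <- aa_t$tau
    }
    H <- rot_about_axis(aa_t$u, head_tau) %*% state_i$H

    # eye: saccade before phase 2, ideal online VOR from phase 2 on
    if (tt < p2_on) {
      f <- growth((tt - s_on) / timing$saccade_duration, kind)
      E <- rot_about_axis(aa_e$u, f * aa_e$tau) %*% state_i$E
    } else {
      E <- invert(H) %*% G_d
    }

    stage[k] <- if (tt >= h_end && tt >= s_end) "done"
      else if (tt >= p2_on) "head_phase2_vor"
      else if (tt >= s_on && tt < s_end) "saccade"
      else if (tt >= h_on) "head_phase1"
      else "pre"

    E_list[[k]] <- E
    H_list[[k]] <- H
  }

  structure(list(time = times,
                 stage = factor(stage, levels = c("pre", "saccade",
                                                  "head_phase1",
                                                  "head_phase2_vor",
                                                  "done")),
                 E = E_list, H = H_list,
                 plan = plan, timing = timing),
            class = "gaze_trajectory")
}

#' @export
print.gaze_trajectory <- function(x, ...) {
  cat(sprintf("Gaze-shift trajectory: %d samples over %.0f ms\n",
              length(x$time), max(x$time)))
  print(table(x$stage))
  invisible(x)
}

#' Component table of a trajectory
#'
#' Flattens a trajectory to one row per sample with eye-in-head, head and
#' gaze orientations expressed both as rotation-vector components
#' (deg; `_tor` torsional/forward axis, `_vert` vertical-rotation, `_horiz`
#' horizontal-rotation) and as Fick angles (deg), plus the gaze-screen
#' intersection (cm).
#'
#' @param x a `gaze_trajectory`.
#' @param row.names,optional,... unused (standard generic arguments).
#' @return `data.frame` with columns `time_ms`, `stage`, `eye_*`, `head_*`,
#'   `gaze_*`, `screen_a_cm`, `screen_b_cm`.
#' @export
as.data.frame.gaze_trajectory <- function(x, row.names = NULL,
                                          optional = FALSE, ...) {
  n <- length(x$time)
  comp <- function(R) {
    r <- rotvec_of(R)
    f <- fick_angles_of(R)
    c(r[1], r[2], r[3], f$theta, f$phi, f$psi)
  }
  out <- matrix(NA_real_, n, 20)
  for (k in seq_len(n)) {
    E <- x$E[[k]]
    H <- x$H[[k]]
    G <- H %*% E
    g <- as.numeric(G %*% c(1, 0, 0))
    scr <- screen_target_from_gaze(.unit(g), x$plan$params$t)
    out[k, ] <- c(comp(E), comp(H), comp(G), scr$a, scr$b)
  }
  nm <- function(p) paste0(p, c("_tor", "_vert", "_horiz",
                                "_fick_theta", "_fick_phi", "_fick_psi"))
  colnames(out) <- c(nm("eye"), nm("head"), nm("gaze"),
                     "screen_a_cm", "screen_b_cm")
  data.frame(time_ms = x$time, stage = x$stage, out,
             stringsAsFactors = FALSE)
}

#' Write a trajectory to CSV
#'
#' Writes the component table of [as.data.frame.gaze_trajectory()] as a
#' comma-separated file ('.' decimal separator, UTF-8, header row). A
#' leading comment block documents the conventions (frame, units, column
#' meanings).
#'
#' @param traj a `gaze_trajectory`.
#' @param file output path.
#' @return the path, invisibly.
#' @export
write_trajectory <- function(traj, file) {
  stopifnot(inherits(traj, "gaze_trajectory"))
  df <- as.data.frame(traj)
  con <- file(file, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(
    "# gaze-shift trajectory",
    "# frame: right-handed, x forward, y left, z up; active rotations",
    "# *_tor/_vert/_horiz: rotation-vector components, deg (torsional = forward axis)",
    "# *_fick_theta/_phi/_psi: Fick angles, deg (psi = Fick torsion)",
    "# screen_a_cm/screen_b_cm: gaze-screen intersection, cm",
    "# time_ms: milliseconds from movement-plan time zero"), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(file)
}

#' Plot a trajectory
#'
#' Two base-graphics panels: component time courses (horizontal, vertical,
#' torsional rotation-vector components of eye, head and gaze) and the
#' torsional-horizontal orientation path.
#'
#' @param x a `gaze_trajectory`.
#' @param ... passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.gaze_trajectory <- function(x, ...) {
  df <- as.data.frame(x)
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::matplot(df$time_ms,
                    df[, c("eye_horiz", "head_horiz", "gaze_horiz",
                           "eye_tor", "head_tor", "gaze_tor")],
                    type = "l", lty = c(1, 1, 1, 2, 2, 2),
                    col = c("red", "darkgreen", "blue"),
                    xlab = "time (ms)", ylab = "component (deg)",
                    main = "horizontal (solid) / torsional (dashed)", ...)
  graphics::legend("topleft", c("eye-in-head", "head", "gaze"),
                   col = c("red", "darkgreen", "blue"), lty = 1, bty = "n")
  graphics::matplot(df[, c("eye_horiz", "head_horiz", "gaze_horiz")],
                    df[, c("eye_tor", "head_tor", "gaze_tor")],
                    type = "l", lty = 1,
                    col = c("red", "darkgreen", "blue"),
                    xlab = "horizontal (deg)", ylab = "torsional (deg)",
                    main = "orientation path")
  invisible(x)
}
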