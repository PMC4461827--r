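# Simulation suites: target-grid range scans of final orientations, twist
# quantification of torsional ranges, and the accuracy / trajectory drivers.

#' Uniform grid of angular targets
#'
#' @param h_range length-2 numeric, horizontal azimuth range, deg.
#' @param v_range length-2 numeric, vertical elevation range, deg.
#' @param n_per_axis points per axis (`n_per_axis^2` targets); 1 yields the
#'   midpoint of each range.
#' @return `data.frame` with columns `gamma`, `eta` (deg).
#' @export
target_grid <- function(h_range = c(-40, 40), v_range = c(-40, 40),
                        n_per_axis = 41) {
  if (max(abs(c(h_range, v_range))) >= 90) {
    stop("target grid must stay within the front hemisphere", call. = FALSE)
  }
  g <- if (n_per_axis == 1) mean(h_range) else
    seq(h_range[1], h_range[2], length.out = n_per_axis)
  e <- if (n_per_axis == 1) mean(v_range) else
    seq(v_range[1], v_range[2], length.out = n_per_axis)
  expand.grid(gamma = g, eta = e, KEEP.OUT.ATTRS = FALSE)
}

.orientation_cols <- function(R, prefix) {
  r <- rotvec_of(R)
  f <- fick_angles_of(R)
  out <- c(r[1], r[2], r[3], f$theta, f$phi, f$psi)
  names(out) <- paste0(prefix, c("_tor", "_vert", "_horiz",
                                 "_fick_theta", "_fick_phi", "_fick_psi"))
  out
}

#' Final-orientation range scan over a target grid
#'
#' Plans one gaze shift per grid target from a common initial state and
#' tabulates the final eye-in-head, head and gaze orientations, each as
#' rotation-vector components and Fick angles (deg).
#'
#' @param params a [gaze_params()].
#' @param grid `data.frame` with `gamma`, `eta` columns (deg), e.g. from
#'   [target_grid()].
#' @param state_i initial [eye_head_state()] (default: reference condition).
#' @return `data.frame` with the target angles and, for each of `eye`,
#'   `head`, `gaze`, columns `_tor`, `_vert`, `_horiz` (rotation-vector
#'   components, deg) and `_fick_theta`, `_fick_phi`, `_fick_psi` (deg).
#' @export
run_range_scan <- function(params = gaze_params(), grid = target_grid(),
                           state_i = eye_head_state()) {
  n <- nrow(grid)
  out <- matrix(NA_real_, n, 18)
  for (k in seq_len(n)) {
    plan <- plan_gaze_shift(state_i,
                            list(gamma = grid$gamma[k], eta = grid$eta[k]),
                            params)
    out[k, ] <- c(.orientation_cols(plan$E_d, "eye"),
                  .orientation_cols(plan$H_d, "head"),
                  .orientation_cols(plan$G_d, "gaze"))
  }
  colnames(out) <- c(names(.orientation_cols(diag(3), "eye")),
                     names(.orientation_cols(diag(3), "head")),
                     names(.orientation_cols(diag(3), "gaze")))
  cbind(grid, as.data.frame(out))
}

#' Twist coefficient of an orientation range
#'
#' Quantifies the "bow-tie" twist of a final-orientation distribution by the
#' least-squares coefficient `k` in
#' `torsion ~ k * horizontal * vertical` (no intercept), computed on the
#' rotation-vector components of a [run_range_scan()] table. Under this
#' package's sign conventions a Fick-like range has `k < 0` and a
#' Helmholtz-like range `k > 0`; a torsion-free (Listing) range gives
#' `k = 0`.
#'
#' @param table output of [run_range_scan()].
#' @param which `"eye"`, `"head"` or `"gaze"`.
#' @return list with `k` (1/deg), `r_squared`, and `degenerate` (`TRUE`
#'   when the table carries no torsion at all, in which case `k = 0`).
#' @export
twist_score <- function(table, which = c("eye", "head", "gaze")) {
  which <- match.arg(which)
  tor <- table[[paste0(which, "_tor")]]
  x <- table[[paste0(which, "_horiz")]] * table[[paste0(which, "_vert")]]
  if (max(abs(tor)) < 1e-12 || max(abs(x)) < 1e-12) {
    return(list(k = 0, r_squared = NA_real_, degenerate = TRUE))
  }
  fit <- stats::lm(tor ~ x - 1)
  list(k = unname(stats::coef(fit)[1]),
       r_squared = summary(fit)$r.squared,
       degenerate = FALSE)
}

#' Initial fixation state at a screen point
#'
#' Builds a Listing/Fick-compliant eye-head state fixating the screen point
#' `(a, b)` by planning (and taking the endpoint of) a preparatory gaze
#' shift from the reference condition with the same coordination
#' parameters. This mimics how a fixation reached by a natural gaze shift
#' distributes the eccentricity between eye and head.
#'
#' @param a,b screen offsets, cm.
#' @param params a [gaze_params()].
#' @return [eye_head_state()].
#' @export
fixation_state_at <- function(a, b, params = gaze_params()) {
  if (a == 0 && b == 0) return(eye_head_state())
  final_state(plan_gaze_shift(eye_head_state(), list(a = a, b = b), params))
}

#' Gaze-accuracy suite: screen targets and fixed retinal errors
#'
#' Simulates rightward gaze shifts from five vertical altitudes in two input
#' modes: `"screen"` (from fixation at `-horizontal_cm` to a target at
#' `+horizontal_cm` on the same altitude) and `"retinal"` (a fixed retinal
#' error imposed from the same five initial fixations). For each shift it
#' returns the trajectory, the gaze-on-screen path, the target-in-retinal-
#' coordinates path, and the final retinal eccentricity of the target.
#'
#' @param condition `"screen"` or `"retinal"`.
#' @param params a [gaze_params()].
#' @param altitudes vertical screen altitudes, cm.
#' @param horizontal_cm half-amplitude of the screen-mode shift, cm.
#' @param retinal_error_deg magnitude of the rightward retinal error in
#'   retinal-mode, deg.
#' @param timing a [timing_profile()].
#' @param n samples per trajectory.
#' @return list of class `"fig_accuracy"`: per shift a list with the
#'   initial state, plan, trajectory, `screen_path` and `retinal_path`
#'   data frames, and `final_retinal_eccentricity_deg`.
#' @details "Rightward" means toward negative azimuth: the frame has +y to
#'   the left, so a target on the right of the screen has `a < 0`.
#' @export
run_fig4 <- function(condition = c("screen", "retinal"),
                     params = gaze_params(),
                     altitudes = c(-40, -20, 0, 20, 40),
                     horizontal_cm = 40,
                     retinal_error_deg = 60,
                     timing = timing_profile(), n = 100) {
  condition <- match.arg(condition)
  shifts <- vector("list", length(altitudes))
  for (i in seq_along(altitudes)) {
    alt <- altitudes[i]
    state_i <- fixation_state_at(horizontal_cm, alt, params)  # +a = left
    if (condition == "screen") {
      target <- list(a = -horizontal_cm, b = alt)
    } else {
      target <- list(retinal_error =
                       dir_from_angles(-retinal_error_deg, 0))
    }
    plan <- plan_gaze_shift(state_i, target, params)
    traj <- simulate(plan, timing = timing, n = n)
    g_d <- plan$g_d

    scr <- matrix(NA_real_, n, 2)
    ret <- matrix(NA_real_, n, 2)
    for (k in seq_len(n)) {
      G <- traj$H[[k]] %*% traj$E[[k]]
      g <- .unit(as.numeric(G %*% c(1, 0, 0)))
      s <- screen_target_from_gaze(g, params$t)
      scr[k, ] <- c(s$a, s$b)
      g_RE <- retinal_error_vector(orthonormalize(G), g_d)
      an <- angles_from_dir(.unit(g_RE))
      ret[k, ] <- c(an$gamma, an$eta)
    }
    final_ecc <- angle_between(
      .unit(as.numeric((traj$H[[n]] %*% traj$E[[n]]) %*% c(1, 0, 0))), g_d)
    shifts[[i]] <- list(
      altitude_cm = alt,
      state_i = state_i,
      plan = plan,
      trajectory = traj,
      screen_path = data.frame(time_ms = traj$time,
                               a_cm = scr[, 1], b_cm = scr[, 2]),
      retinal_path = data.frame(time_ms = traj$time,
                                gamma = ret[, 1], eta = ret[, 2]),
      final_retinal_eccentricity_deg = final_ecc
    )
  }
  structure(list(condition = condition, params = params,
                 altitudes = altitudes, shifts = shifts),
            class = "fig_accuracy")
}

#' @export
print.fig_accuracy <- function(x, ...) {
  cat(sprintf("Gaze-accuracy suite (%s input mode), %d shifts\n",
              x$condition, length(x$shifts)))
  ecc <- vapply(x$shifts, `[[`, numeric(1),
                "final_retinal_eccentricity_deg")
  cat(sprintf("  final retinal eccentricity: max %.3e deg\n", max(ecc)))
  invisible(x)
}

#' Trajectory suite between two vertical target columns
#'
#' Plans and simulates all shifts from fixations in a left screen column to
#' targets in a right screen column (default three altitudes each, nine
#' shifts), reproducing the oblique-shift torsion transients: the eye leaves
#' Listing's plane during the saccade and returns by the VOR, while the head
#' leaves the zero-torsion Fick surface mid-flight.
#'
#' @param params a [gaze_params()].
#' @param from_cm horizontal screen offset of the initial column, cm.
#' @param to_cm horizontal offset of the target column, cm.
#' @param altitudes vertical altitudes of both columns, cm.
#' @param timing a [timing_profile()].
#' @param n samples per trajectory.
#' @return list of trajectories; each element carries `from_cm`,
#'   `from_alt`, `to_alt`, the plan and the `gaze_trajectory`.
#' @export
run_trajectory_suite <- function(params = gaze_params(),
                                 from_cm = 40, to_cm = -40,
                                 altitudes = c(-40, 0, 40),
                                 timing = timing_profile(), n = 100) {
  out <- list()
  for (a_from in altitudes) {
    state_i <- fixation_state_at(from_cm, a_from, params)
    for (a_to in altitudes) {
      plan <- plan_gaze_shift(state_i, list(a = to_cm, b = a_to), params)
      traj <- simulate(plan, timing = timing, n = n)
      out[[length(out) + 1L]] <- list(from_cm = from_cm, from_alt = a_from,
                                      to_cm = to_cm, to_alt = a_to,
                                      plan = plan, trajectory = traj)
    }
  }
  out
}

#' Plot an orientation range scan
#'
#' Base-graphics panel row in the style of the torsional range figures:
#' for eye-in-head, head and gaze, the horizontal rotation-vector component
#' against the torsional component, with the top grid row highlighted.
#'
#' @param table output of [run_range_scan()].
#' @param main overall title.
#' @return invisibly, `table`.
#' @export
plot_range_scan <- function(table, main = "final orientation ranges") {
  op <- graphics::par(mfrow = c(1, 3), mar = c(4, 4, 3, 1),
                      oma = c(0, 0, 2, 0))
  on.exit(graphics::par(op))
  cols <- c(eye = "red", head = "darkgreen", gaze = "blue")
  top <- table$eta == max(table$eta)
  for (which in names(cols)) {
    h <- table[[paste0(which, "_horiz")]]
    tor <- table[[paste0(which, "_tor")]]
    graphics::plot(h, tor, pch = 16, cex = 0.4, col = cols[[which]],
                   xlab = "horizontal (deg)", ylab = "torsional (deg)",
                   main = which)
    graphics::lines(h[top][order(h[top])], tor[top][order(h[top])],
                    col = "black", lwd = 2)
  }
  graphics::mtext(main, outer = TRUE)
  invisible(table)
}
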