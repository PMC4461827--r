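# Seeded generator of valid random initial states and targets.
#
# The generator emulates the study's initial conditions: fixations reached
# by natural gaze shifts, i.e. eye-in-head orientations in Listing's plane
# and head orientations with zero Fick torsion, at bounded eccentricity,
# with targets on the central portion of the screen.

#' Random valid eye-head states and targets
#'
#' Draws `n` initial states whose eye-in-head orientation is
#' Listing-compliant (rotation axis in Listing's plane) and whose head
#' orientation has zero Fick torsion, plus `n` angular targets. Eye and
#' head direction eccentricities are bounded by `max_ecc` (deg) and target
#' angles are uniform in `target_range` (deg per axis). Reproducible: the
#' same `seed` yields the same batch; the caller's RNG state is left
#' untouched.
#'
#' @param n number of draws.
#' @param seed integer seed.
#' @param max_ecc eccentricity bound for eye and head directions, deg.
#' @param target_range length-2 range for both target angles, deg.
#' @return list with `states` (list of [eye_head_state()]) and `targets`
#'   (`data.frame` with `gamma`, `eta`, deg).
#' @export
random_fixtures <- function(n, seed = 1L, max_ecc = 45,
                            target_range = c(-40, 40)) {
  if (n <= 0) stop("'n' must be positive", call. = FALSE)
  if (max_ecc <= 0 || max_ecc >= 90) {
    stop("'max_ecc' must be in (0, 90) degrees", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)

  # uniform direction within a spherical cap of half-angle max_ecc about +x
  draw_dir <- function() {
    ecc <- .rad2deg(acos(1 - stats::runif(1) *
                           (1 - cos(.deg2rad(max_ecc * 0.999)))))
    ang <- stats::runif(1, 0, 360)
    rot_about_axis(c(1, 0, 0), ang) %*%
      dir_from_angles(0, ecc)
  }

  states <- vector("list", n)
  for (k in seq_len(n)) {
    e_dir <- as.numeric(draw_dir())
    h_dir <- as.numeric(draw_dir())
    states[[k]] <- eye_head_state(
      E = listing_orientation_from_dir(e_dir),
      H = fick_orientation_from_dir(h_dir))
  }
  targets <- data.frame(
    gamma = stats::runif(n, target_range[1], target_range[2]),
    eta = stats::runif(n, target_range[1], target_range[2]))
  list(states = states, targets = targets)
}
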