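# Serialization: gaze-plan records (JSON), run configurations (YAML in,
# resolved JSON echo out).
#
# Conventions: matrices row-major, angles deg, distances cm, times ms.

PLAN_SCHEMA_VERSION <- "1.0"

.mat_to_row_major <- function(R) as.numeric(t(R))
.mat_from_row_major <- function(v) matrix(as.numeric(v), 3, 3, byrow = TRUE)

#' Serialize a gaze plan
#'
#' Converts a `gaze_plan` to a plain list (and, with [write_gaze_plan()],
#' a JSON record): all rotation matrices row-major, displacement commands
#' in degrees, full parameter provenance, and a schema version.
#'
#' @param plan a `gaze_plan`.
#' @return nested list ready for JSON encoding.
#' @export
plan_to_list <- function(plan) {
  stopifnot(inherits(plan, "gaze_plan"))
  mats <- c("Re", "Rh", "Rw", "Rt", "Rv", "Ra", "E_d", "H_d", "G_d")
  rec <- list(
    schema = "gazekin/plan",
    schema_version = PLAN_SCHEMA_VERSION,
    units = list(angles = "deg", distances = "cm"),
    matrix_layout = "row-major",
    params = unclass(plan$params),
    target = list(mode = plan$target$mode,
                  g_d = as.numeric(plan$g_d),
                  gaze_angles = plan$c_d,
                  head_angles = plan$b_d),
    initial = list(E = .mat_to_row_major(plan$state_i$E),
                   H = .mat_to_row_major(plan$state_i$H)),
    rotations = stats::setNames(
      lapply(mats, function(nm) .mat_to_row_major(plan[[nm]])), mats),
    displacement = list(dE = plan$dE, dH = plan$dH),
    residuals = as.list(residuals(plan))
  )
  rec
}

#' @rdname plan_to_list
#' @param file output path for the JSON record.
#' @return `write_gaze_plan()` returns the path, invisibly.
#' @export
write_gaze_plan <- function(plan, file) {
  jsonlite::write_json(plan_to_list(plan), file, auto_unbox = TRUE,
                       digits = I(17), pretty = TRUE)
  invisible(file)
}

#' Read a serialized gaze plan
#'
#' Reconstructs the rotation matrices and commands from a JSON record
#' written by [write_gaze_plan()].
#'
#' @param file path to the JSON record.
#' @return list with the same fields as [plan_to_list()] but matrices
#'   restored to 3 x 3 form.
#' @export
read_gaze_plan <- function(file) {
  rec <- jsonlite::read_json(file, simplifyVector = TRUE)
  if (!identical(rec$schema, "gazekin/plan")) {
    stop("not a gazekin plan record", call. = FALSE)
  }
  rec$initial$E <- .mat_from_row_major(rec$initial$E)
  rec$initial$H <- .mat_from_row_major(rec$initial$H)
  rec$rotations <- lapply(rec$rotations, .mat_from_row_major)
  rec
}

#' Load a run configuration
#'
#' Reads a YAML run configuration and resolves it against the defaults.
#' Recognized blocks: `params` (`alpha`, `beta`, `delta`, `t`), `timing`
#' (see [timing_profile()]), `initial_state`, `target`, `n_samples`,
#' `seed`. `initial_state` is one of `type: reference`,
#' `type: angles` (fields `eye_gamma`, `eye_eta`, `head_theta`,
#' `head_phi`: a Listing-compliant eye and zero-torsion Fick head), or
#' `type: random` (drawn with [random_fixtures()] from `seed`). `target`
#' is one of `type: screen` (`a`, `b` in cm), `type: angles`
#' (`gamma`, `eta` in deg) or `type: retinal_error` (`gamma`, `eta` of the
#' retinal direction, deg).
#'
#' @param path YAML file path.
#' @return list of class `"run_config"` with resolved `params`, `timing`,
#'   `state_i`, `target`, `n_samples`, `seed`.
#' @export
load_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  resolve_run_config(raw)
}

#' @rdname load_run_config
#' @param raw a configuration list (as parsed from YAML).
#' @export
resolve_run_config <- function(raw) {
  if (is.null(raw)) raw <- list()
  p <- raw$params
  params <- tryCatch(
    gaze_params(alpha = p$alpha %||% 0.5, beta = p$beta %||% 0.5,
                delta = p$delta %||% 0.5, t = p$t %||% 100),
    error = function(e) stop("invalid 'params': ", conditionMessage(e),
                             call. = FALSE))
  tm <- raw$timing
  timing <- tryCatch(
    timing_profile(
      saccade_onset = tm$saccade_onset %||% 0,
      saccade_duration = tm$saccade_duration %||% 100,
      head_onset = tm$head_onset %||% 0,
      head_phase1_duration = tm$head_phase1_duration %||% 150,
      head_phase2_duration = tm$head_phase2_duration %||% 250,
      growth_kind = tm$growth_kind %||% "smoothstep"),
    error = function(e) stop("invalid 'timing': ", conditionMessage(e),
                             call. = FALSE))
  seed <- raw$seed %||% 1L

  st <- raw$initial_state %||% list(type = "reference")
  state_i <- switch(st$type %||% "reference",
    reference = eye_head_state(),
    angles = eye_head_state(
      E = listing_orientation_from_dir(
        dir_from_angles(st$eye_gamma %||% 0, st$eye_eta %||% 0)),
      H = fick_matrix(st$head_theta %||% 0, st$head_phi %||% 0, 0)),
    random = random_fixtures(1, seed = st$seed %||% seed)$states[[1]],
    stop(sprintf("invalid 'initial_state': unknown type '%s'", st$type),
         call. = FALSE))

  tg <- raw$target %||% list(type = "screen", a = 0, b = 0)
  target <- switch(tg$type %||% "screen",
    screen = list(a = tg$a %||% 0, b = tg$b %||% 0),
    angles = list(gamma = tg$gamma %||% 0, eta = tg$eta %||% 0),
    retinal_error = list(retinal_error =
      dir_from_angles(tg$gamma %||% 0, tg$eta %||% 0)),
    stop(sprintf("invalid 'target': unknown type '%s'", tg$type),
         call. = FALSE))

  structure(list(params = params, timing = timing, state_i = state_i,
                 target = target, n_samples = raw$n_samples %||% 200,
                 seed = seed),
            class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Echo a resolved configuration as JSON
#'
#' Writes the fully resolved configuration (after defaulting) next to a
#' run's outputs so that every run is reproducible from its sidecar alone.
#'
#' @param config a `run_config`.
#' @param file output path.
#' @return the path, invisibly.
#' @export
write_config_sidecar <- function(config, file) {
  stopifnot(inherits(config, "run_config"))
  rec <- list(schema = "gazekin/run-config",
              schema_version = PLAN_SCHEMA_VERSION,
              params = unclass(config$params),
              timing = unclass(config$timing),
              initial = list(E = .mat_to_row_major(config$state_i$E),
                             H = .mat_to_row_major(config$state_i$H)),
              target = config$target,
              n_samples = config$n_samples,
              seed = config$seed)
  jsonlite::write_json(rec, file, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(file)
}
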