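ref <- eye_head_state()
p_half <- gaze_params(0.5, 0.5, 0.5)
rz <- function(a) rot_about_axis(c(0, 0, 1), a)

test_that("desired head angles interpolate between head and gaze positions", {
  cases <- list(
    list(b_i = c(gamma = 0, eta = 0), c_d = c(gamma = 40, eta = 0),
         a = 0.5, b = 0.5, want = c(20, 0)),
    list(b_i = c(gamma = 0, eta = 0), c_d = c(gamma = 35, eta = -12),
         a = 1, b = 1, want = c(35, -12)),
    list(b_i = c(gamma = 10, eta = -5), c_d = c(gamma = 30, eta = 15),
         a = 0.3, b = 0.6, want = c(16, 7)))
  for (cs in cases) {
    got <- desired_head_angles(cs$b_i, cs$c_d, cs$a, cs$b)
    expect_equal(c(got$gamma, got$eta), cs$want, tolerance = 1e-12)
  }
})

test_that("zero-torsion Fick orientation points the head at its direction", {
  expect_equal(fick_orientation_from_dir(c(1, 0, 0)), diag(3),
               tolerance = 1e-12)
  expect_equal(fick_orientation_from_dir(dir_from_angles(30, 0)), rz(30),
               tolerance = 1e-12)
  H <- fick_orientation_from_dir(dir_from_angles(30, 30))
  f <- fick_angles_of(H)
  expect_equal(c(f$theta, f$phi, f$psi), c(30, -30, 0), tolerance = 1e-9)
  expect_equal(as.numeric(H %*% c(1, 0, 0)), dir_from_angles(30, 30),
               tolerance = 1e-12)
  expect_equal(quat_of_matrix(H)[2],
               -sin(15 * pi / 180) * sin(-15 * pi / 180), tolerance = 1e-12)
  expect_error(fick_orientation_from_dir(c(0, 0, 1)), "imbal")
})

test_that("Listing orientation points the eye with zero torsion", {
  expect_equal(listing_orientation_from_dir(c(1, 0, 0)), diag(3))
  c40 <- cos(40 * pi / 180); s40 <- sin(40 * pi / 180)
  E <- listing_orientation_from_dir(c(c40, 0, s40))
  expect_lt(frob(E, rot_about_axis(c(0, -1, 0), 40)), 1e-12)
  c30 <- cos(30 * pi / 180); s30 <- sin(30 * pi / 180)
  expect_lt(frob(listing_orientation_from_dir(c(c30, s30, 0)), rz(30)),
            1e-12)
  expect_error(listing_orientation_from_dir(c(-1, 0, 0)), "180")
  set.seed(61)
  for (k in 1:200) {
    d <- dir_from_angles(stats::runif(1, -85, 85), stats::runif(1, -85, 85))
    E <- listing_orientation_from_dir(d)
    expect_equal(as.numeric(E %*% c(1, 0, 0)), d, tolerance = 1e-9)
    expect_lt(abs(listing_torsion(E)), 1e-10)
  }
})

test_that("fixed-axis rotation split is coaxial and recomposes", {
  sp <- split_rotation(rz(30), 0.5)
  expect_lt(frob(sp$Rh, rz(15)), 1e-12)
  expect_lt(frob(sp$Rw, rz(15)), 1e-12)
  sp <- split_rotation(rz(30), 1)
  expect_lt(frob(sp$Rh, rz(30)), 1e-12)
  expect_lt(frob(sp$Rw, diag(3)), 1e-12)
  set.seed(67)
  for (k in 1:100) {
    Rt <- random_rotation(max_tau = 170)
    d <- stats::runif(1)
    sp <- split_rotation(Rt, d)
    expect_lt(frob(compose(sp$Rw, sp$Rh), Rt), 1e-9)
    expect_equal(axis_angle_of(sp$Rh)$tau, d * axis_angle_of(Rt)$tau,
                 tolerance = 1e-9)
  }
})

test_that("the VOR rotation preserves the full 3-D gaze orientation", {
  # delta = 1: no second head phase, no VOR
  expect_lt(frob(vor_rotation(diag(3), rz(30), diag(3)), diag(3)), 1e-12)
  # coaxial closed form
  expect_lt(frob(vor_rotation(diag(3), rz(15), rz(15)), rz(-15)), 1e-12)
  # oblique: desired-condition gaze equals the after-second-stage gaze
  set.seed(71)
  for (k in 1:50) {
    fx <- random_fixtures(1, seed = k)
    st <- fx$states[[1]]
    Rt <- random_rotation(max_tau = 60)
    sp <- split_rotation(Rt, stats::runif(1))
    Rv <- vor_rotation(st$H, sp$Rh, sp$Rw)
    Re <- random_rotation(max_tau = 60)
    lhs <- compose(sp$Rw, sp$Rh, st$H, Rv, Re, st$E)
    rhs <- compose(sp$Rh, st$H, Re, st$E)
    expect_lt(frob(lhs, rhs), 1e-9)
  }
})

test_that("planning to the current fixation point is the identity plan", {
  plan <- plan_gaze_shift(ref, list(a = 0, b = 0), p_half)
  for (nm in c("Re", "Rh", "Rw", "Rt", "Rv", "E_d", "H_d", "G_d")) {
    expect_lt(frob(plan[[nm]], diag(3)), 1e-12)
  }
  dc <- displacement_commands(plan)
  expect_equal(dc$dE, c(0, 0, 0))
  expect_equal(dc$dH, c(0, 0, 0))
})

test_that("the coaxial 60-degree shift has the closed-form stage split", {
  plan <- plan_gaze_shift(ref, list(gamma = 60, eta = 0), p_half)
  expect_lt(frob(plan$Re, rz(45)), 1e-12)
  expect_lt(frob(plan$Rh, rz(15)), 1e-12)
  expect_lt(frob(plan$Rw, rz(15)), 1e-12)
  expect_lt(frob(plan$Rv, rz(-15)), 1e-12)
  expect_lt(frob(plan$E_d, rz(30)), 1e-12)
  expect_lt(frob(plan$H_d, rz(30)), 1e-12)
  expect_equal(displacement_commands(plan)$dH, c(0, 0, 30),
               tolerance = 1e-12)
})

test_that("oblique plans satisfy every desired-condition composition", {
  plan <- plan_gaze_shift(ref, list(gamma = 40, eta = 40), p_half)
  # structural identities
  expect_lt(frob(plan$Rt, compose(plan$Rw, plan$Rh)), 1e-9)
  expect_lt(frob(plan$Ra, compose(plan$Rv, plan$Re)), 1e-9)
  expect_lt(frob(plan$E_d, compose(plan$Rv, plan$Re, ref$E)), 1e-9)
  expect_lt(frob(plan$H_d, compose(plan$Rw, plan$Rh, ref$H)), 1e-9)
  expect_lt(frob(plan$G_d, plan$H_d %*% plan$E_d), 1e-12)
  # constraints
  r <- residuals(plan)
  expect_lt(r[["gaze_error"]], 1e-7)
  expect_lt(abs(r[["listing_torsion"]]), 1e-9)
  expect_lt(abs(r[["fick_torsion"]]), 1e-9)
  # the post-saccadic eye has torsion that the predicted VOR cancels
  expect_gt(abs(listing_torsion(plan$Re %*% ref$E)), 0.1)
})

test_that("random plans foveate the target under the stage-table oracle", {
  fx <- random_fixtures(300, seed = 73)
  set.seed(79)
  worst <- c(acc = 0, listing = 0, fick = 0)
  for (k in 1:300) {
    params <- gaze_params(stats::runif(1), stats::runif(1), stats::runif(1))
    st <- fx$states[[k]]
    plan <- plan_gaze_shift(st, list(gamma = fx$targets$gamma[k],
                                     eta = fx$targets$eta[k]), params)
    # brute-force stage-table compositions
    expect_lt(frob(plan$E_d, compose(plan$Rv, plan$Re, st$E)), 1e-9)
    expect_lt(frob(plan$H_d, compose(plan$Rw, plan$Rh, st$H)), 1e-9)
    expect_lt(frob(plan$G_d,
                   compose(plan$Rw, plan$Rh, st$H, plan$Rv, plan$Re, st$E)),
              1e-9)
    acc <- angle_between(unitize(as.numeric(plan$G_d %*% c(1, 0, 0))),
                         plan$g_d)
    worst <- pmax(worst, c(acc, abs(listing_torsion(plan$E_d)),
                           abs(fick_torsion(plan$H_d))))
  }
  expect_lt(worst[["acc"]], 1e-7)
  expect_lt(worst[["listing"]], 1e-9)
  expect_lt(worst[["fick"]], 1e-9)
})

test_that("delta only redistributes the saccade/VOR split, never the endpoints", {
  fx <- random_fixtures(40, seed = 83)
  for (k in 1:40) {
    st <- fx$states[[k]]
    target <- list(gamma = fx$targets$gamma[k], eta = fx$targets$eta[k])
    plans <- lapply(c(0.1, 0.5, 0.9), function(d)
      plan_gaze_shift(st, target, gaze_params(0.4, 0.7, d)))
    for (i in 2:3) {
      expect_identical(plans[[i]]$E_d, plans[[1]]$E_d)
      expect_identical(plans[[i]]$H_d, plans[[1]]$H_d)
      expect_identical(plans[[i]]$G_d, plans[[1]]$G_d)
    }
    # but the split itself moves
    expect_gt(frob(plans[[1]]$Re, plans[[3]]$Re), 1e-6)
  }
})

test_that("boundary coordination weights close the model limits", {
  # head points at the target, eye returns to primary position
  fx <- random_fixtures(20, seed = 89)
  for (k in 1:20) {
    plan <- plan_gaze_shift(fx$states[[k]],
                            list(gamma = fx$targets$gamma[k],
                                 eta = fx$targets$eta[k]),
                            gaze_params(1, 1, 0.5))
    expect_lt(frob(plan$E_d, diag(3)), 1e-9)
    # head-fixed saccade: head does not move at all
    plan0 <- plan_gaze_shift(fx$states[[k]],
                             list(gamma = fx$targets$gamma[k],
                                  eta = fx$targets$eta[k]),
                             gaze_params(0, 0, 0.5))
    expect_lt(frob(plan0$H_d, fx$states[[k]]$H), 1e-9)
    expect_lt(frob(plan0$Rt, diag(3)), 1e-9)
  }
})

test_that("displacement commands are consistent rotation-vector differences", {
  plan <- plan_gaze_shift(ref, list(gamma = 40, eta = 40), p_half)
  dc <- displacement_commands(plan)
  # reconstruct the post-saccadic eye orientation from the command
  E_sacc <- rotation_from_rotvec(rotvec_of(ref$E) + dc$dE)
  d1 <- unitize(as.numeric(E_sacc %*% c(1, 0, 0)))
  d2 <- unitize(as.numeric(plan$Re %*% ref$E %*% c(1, 0, 0)))
  expect_lt(angle_between(d1, d2), 1e-9)
  H_rec <- rotation_from_rotvec(rotvec_of(ref$H) + dc$dH)
  expect_lt(frob(H_rec, plan$H_d), 1e-9)
})

test_that("invalid inputs are rejected with informative errors", {
  expect_error(gaze_params(alpha = 1.5), "alpha")
  expect_error(gaze_params(beta = -0.1), "beta")
  expect_error(gaze_params(t = 0), "t")
  expect_error(plan_gaze_shift(ref, list(gamma = 120, eta = 0), p_half),
               "hemisphere")
  # head stays put far from a very eccentric target: eye would have to
  # leave the front hemisphere of the head
  st <- eye_head_state(H = rot_about_axis(c(0, 0, 1), -80))
  expect_error(plan_gaze_shift(st, list(gamma = 85, eta = 0),
                               gaze_params(0, 0, 0.5)),
               "unreachable")
  expect_error(plan_gaze_shift(ref, list(bogus = 1), p_half), "target")
})

test_that("plan methods report the solution coherently", {
  plan <- plan_gaze_shift(ref, list(gamma = 60, eta = 0), p_half)
  s <- summary(plan)
  expect_equal(unname(s$magnitudes["saccade"]), 45, tolerance = 1e-9)
  expect_equal(unname(s$magnitudes["head_total"]), 30, tolerance = 1e-9)
  expect_equal(unname(s$magnitudes["vor"]), 15, tolerance = 1e-9)
  expect_output(print(plan), "saccade")
  expect_output(print(s), "residuals")
  co <- coef(plan)
  expect_equal(unname(co["dH_horizontal"]), 30, tolerance = 1e-9)
  pr <- predict(plan)
  expect_equal(pr$gaze_angles$gamma, 60, tolerance = 1e-9)
  expect_output(print(final_state(plan)), "gaze direction")
})
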