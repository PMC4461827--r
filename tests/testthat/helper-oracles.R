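# Independent oracles used across the suite. Quaternions are deliberately
# kept out of the package API; here they serve as a cross-check route for
# the matrix algebra.

# unit quaternion (w, x, y, z) from a rotation matrix, Shepperd's method
quat_of_matrix <- function(R) {
  tr <- sum(diag(R))
  cand <- c(tr, R[1, 1], R[2, 2], R[3, 3])
  i <- which.max(cand)
  if (i == 1) {
    s <- sqrt(tr + 1) * 2
    q <- c(s / 4, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (i == 2) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, s / 4, (R[1, 2] + R[2, 1]) / s,
           (R[1, 3] + R[3, 1]) / s)
  } else if (i == 3) {
    s <- sqrt(1 - R[1, 1] + R[2, 2] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s, s / 4,
           (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 - R[1, 1] - R[2, 2] + R[3, 3]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, s / 4)
  }
  if (q[1] < 0) q <- -q
  q / sqrt(sum(q^2))
}

# Hamilton product
quat_mult <- function(p, q) {
  c(p[1] * q[1] - sum(p[2:4] * q[2:4]),
    p[1] * q[2:4] + q[1] * p[2:4] +
      c(p[3] * q[4] - p[4] * q[3],
        p[4] * q[2] - p[2] * q[4],
        p[2] * q[3] - p[3] * q[2]))
}

quat_about_axis <- function(u, tau_deg) {
  h <- tau_deg * pi / 360
  c(cos(h), sin(h) * u / sqrt(sum(u^2)))
}

# axis/angle (deg) from a unit quaternion, w >= 0
axis_angle_of_quat <- function(q) {
  if (q[1] < 0) q <- -q
  s <- sqrt(sum(q[2:4]^2))
  if (s < 1e-15) return(list(u = c(0, 0, 1), tau = 0))
  list(u = q[2:4] / s, tau = 2 * atan2(s, q[1]) * 180 / pi)
}

frob <- function(A, B = 0) sqrt(sum((A - B)^2))

unitize <- function(v) v / sqrt(sum(v^2))

# seeded random rotation via uniform axis and angle
random_rotation <- function(max_tau = 179) {
  u <- unitize(stats::rnorm(3))
  rot_about_axis(u, stats::runif(1, 0, max_tau))
}

gaze_dir_of <- function(E, H) unitize(as.numeric(H %*% E %*% c(1, 0, 0)))
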