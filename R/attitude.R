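#' Rotation and tilt mathematics for body-worn sensors
#'
#' The attitude of every body segment is described by roll/pitch/yaw Euler
#' angles in the aerospace (yaw-pitch-roll, Z-Y-X) sequence, relating the
#' sensor body frame (x forward, y right, z down) to a local-level
#' navigation frame (forward-across-down with arbitrary heading origin).
#' These helpers convert between Euler angles and direction cosine
#' matrices, and derive tilt from the accelerometer and heading from the
#' magnetometer.
#'
#' @name attitude
NULL

check_finite <- function(x, what) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    abort(sprintf("`%s` must be finite and numeric", what),
          class = "gaitkin_invalid_argument")
  }
  invisible(x)
}

#' Wrap angles to (-pi, pi]
#'
#' @param x angles in radians.
#' @return Wrapped angles, same shape as `x`.
#' @export
wrap_angle <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  # keep +pi rather than -pi so the interval is (-pi, pi]
  y[y == -pi] <- pi
  y
}

#' Skew-symmetric (cross-product) matrix of a 3-vector
#'
#' @param v numeric length-3 vector.
#' @return 3x3 matrix `S` with `S %*% w == v x w`.
#' @export
skew <- function(v) {
  check_finite(v, "v")
  stopifnot(length(v) == 3)
  matrix(c(0, -v[3], v[2],
           v[3], 0, -v[1],
           -v[2], v[1], 0), nrow = 3, byrow = TRUE)
}

#' Direction cosine matrix from Euler angles
#'
#' Builds the body-to-local-level rotation matrix for the aerospace
#' yaw-pitch-roll sequence. Columns are body axes expressed in the
#' local-level frame; the third row is
#' `(-sin(theta), sin(phi) cos(theta), cos(phi) cos(theta))`.
#'
#' @param roll,pitch,yaw Euler angles in radians. `pitch` must lie in
#'   `[-pi/2, pi/2]`.
#' @return A 3x3 orthonormal rotation matrix with determinant +1.
#' @examples
#' dcm_from_euler(0, 0, 0)            # identity
#' dcm_from_euler(0, pi / 4, 0)[3, ]  # (-sqrt(2)/2, 0, sqrt(2)/2)
#' @export
dcm_from_euler <- function(roll, pitch, yaw) {
  check_finite(c(roll, pitch, yaw), "angles")
  cph <- cos(roll);  sph <- sin(roll)
  cth <- cos(pitch); sth <- sin(pitch)
  cps <- cos(yaw);   sps <- sin(yaw)
  matrix(c(
    cth * cps, -cph * sps + sph * sth * cps,  sph * sps + cph * sth * cps,
    cth * sps,  cph * cps + sph * sth * sps, -sph * cps + cph * sth * sps,
    -sth,       sph * cth,                    cph * cth
  ), nrow = 3, byrow = TRUE)
}

#' Euler angles from a direction cosine matrix
#'
#' Inverse of [dcm_from_euler()]. Fails on gimbal lock
#' (`|R[3,1]|` within `1e-9` of 1), where roll and yaw are not separable.
#'
#' @param R 3x3 body-to-local-level rotation matrix.
#' @return Named numeric vector `c(roll, pitch, yaw)` in radians.
#' @export
euler_from_dcm <- function(R) {
  stopifnot(is.matrix(R), all(dim(R) == c(3, 3)))
  check_finite(R, "R")
  if (abs(R[3, 1]) >= 1 - 1e-9) {
    abort("attitude is at gimbal lock (|pitch| = pi/2); Euler angles undefined",
          class = "gaitkin_degenerate_attitude")
  }
  c(roll  = atan2(R[3, 2], R[3, 3]),
    pitch = asin(-R[3, 1]),
    yaw   = atan2(R[2, 1], R[1, 1]))
}

#' Roll and pitch from a specific-force measurement
#'
#' At rest the accelerometer senses `f = C' (0, 0, -g)`, so the tilt can
#' be recovered as `roll = atan2(-fy, -fz)` and
#' `pitch = atan2(fx, sqrt(fy^2 + fz^2))`. The positive square-root
#' denominator keeps pitch in `[-pi/2, pi/2]`.
#'
#' @param f numeric length-3 specific-force vector (m/s^2), body frame.
#' @return Named vector `c(roll, pitch)` in radians.
#' @examples
#' tilt_from_accel(c(0, 0, -9.80665))  # level: c(0, 0)
#' @export
tilt_from_accel <- function(f) {
  check_finite(f, "f")
  stopifnot(length(f) == 3)
  f <- unname(f)
  if (sqrt(sum(f^2)) == 0) {
    abort("zero specific-force vector carries no tilt information",
          class = "gaitkin_invalid_argument")
  }
  c(roll  = atan2(-f[2], -f[3]),
    pitch = atan2(f[1], sqrt(f[2]^2 + f[3]^2)))
}

#' Heading from a magnetometer measurement
#'
#' Tilt-compensated heading: the body-frame magnetic field is levelled
#' with the current roll and pitch and the yaw follows from a
#' four-quadrant arctangent of
#' `(-my cos(phi) + mz sin(phi)) / (mx cos(theta) + my sin(phi) sin(theta)
#'  + mz cos(phi) sin(theta))`.
#' Magnetic declination is ignored: yaw is a local, arbitrary heading.
#'
#' @param m numeric length-3 magnetic field vector (any consistent unit).
#' @param roll,pitch current attitude in radians.
#' @return Yaw angle in radians, in `(-pi, pi]`.
#' @export
yaw_from_mag <- function(m, roll, pitch) {
  check_finite(m, "m"); check_finite(c(roll, pitch), "roll/pitch")
  stopifnot(length(m) == 3)
  if (sqrt(sum(m^2)) == 0) {
    abort("zero magnetic-field vector carries no heading information",
          class = "gaitkin_invalid_argument")
  }
  num <- -m[2] * cos(roll) + m[3] * sin(roll)
  den <- m[1] * cos(pitch) + m[2] * sin(roll) * sin(pitch) +
    m[3] * cos(roll) * sin(pitch)
  if (abs(num) < 1e-12 && abs(den) < 1e-12) {
    abort("magnetic field is parallel to the vertical; heading undefined",
          class = "gaitkin_degenerate_field")
  }
  atan2(num, den)
}
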