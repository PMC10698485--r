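#' Elementary passive rotation matrices
#'
#' Passive (frame) rotations about the body axes, in degrees. These are the
#' building blocks of the direction cosine matrix: for a passive intrinsic
#' rotation applied in yaw-pitch-roll (z-y-x) order,
#' \eqn{D_{ib} = R_x(\phi)\,R_y(\theta)\,R_z(\varphi)} maps inertial (NED)
#' vectors into the body (surge-sway-heave) frame.
#'
#' @param angle Rotation angle in degrees.
#' @return A 3x3 orthonormal rotation matrix (determinant +1).
#' @examples
#' rot_z(90)             # first row (0, 1, 0)
#' rot_x(30) %*% rot_x(-30)  # identity
#' @export
rot_z <- function(angle) {
  c <- cosd(angle); s <- sind(angle)
  matrix(c(c, s, 0,
           -s, c, 0,
           0, 0, 1), nrow = 3, byrow = TRUE)
}

#' @rdname rot_z
#' @export
rot_y <- function(angle) {
  c <- cosd(angle); s <- sind(angle)
  matrix(c(c, 0, -s,
           0, 1, 0,
           s, 0, c), nrow = 3, byrow = TRUE)
}

#' @rdname rot_z
#' @export
rot_x <- function(angle) {
  c <- cosd(angle); s <- sind(angle)
  matrix(c(1, 0, 0,
           0, c, s,
           0, -s, c), nrow = 3, byrow = TRUE)
}

#' Direction cosine matrix from Euler angles
#'
#' Composes the inertial-to-body DCM for the passive intrinsic yaw-pitch-roll
#' convention: `rot_x(roll) %*% rot_y(pitch) %*% rot_z(yaw)`.
#'
#' @param yaw,pitch,roll Euler angles in degrees.
#' @return A 3x3 orthonormal matrix with determinant +1.
#' @examples
#' dcm_ib(0, 0, 0)        # identity
#' dcm_ib(30, 0, 0)[1, ]  # (cos 30, sin 30, 0)
#' @export
dcm_ib <- function(yaw, pitch, roll) {
  rot_x(roll) %*% rot_y(pitch) %*% rot_z(yaw)
}

#' Predict body-frame magnetometer readings from attitude
#'
#' The forward rotation model \eqn{H_b = D_{ib} H_i}: given the local
#' reference field and the bird's Euler angles, returns the field the
#' magnetometer would measure on its surge (x), sway (y) and heave (z) axes.
#' Vectorized over the angle arguments (recycled to a common length).
#'
#' @param field A [reference_field()].
#' @param yaw,pitch,roll Euler angles in degrees (vectors are recycled).
#' @return A tibble with columns `h_x`, `h_y`, `h_z` (nT), one row per
#'   angle triple.
#' @examples
#' f <- reference_field(11355, -10954, -27690)
#' forward_model(f, 0, 0, 0)  # identity rotation returns the field itself
#' @export
forward_model <- function(field, yaw, pitch = 0, roll = 0) {
  stopifnot(is_reference_field(field))
  n <- max(length(yaw), length(pitch), length(roll))
  yaw <- rep_len(yaw, n); pitch <- rep_len(pitch, n); roll <- rep_len(roll, n)
  cph <- cosd(yaw); sph <- sind(yaw)
  cth <- cosd(pitch); sth <- sind(pitch)
  cro <- cosd(roll); sro <- sind(roll)
  hn <- field$h_n; he <- field$h_e; hd <- field$h_d
  tibble::tibble(
    h_x = cth * cph * hn + cth * sph * he - sth * hd,
    h_y = (sro * sth * cph - cro * sph) * hn +
      (sro * sth * sph + cro * cph) * he + sro * cth * hd,
    h_z = (cro * sth * cph + sro * sph) * hn +
      (cro * sth * sph - sro * cph) * he + cro * cth * hd
  )
}
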