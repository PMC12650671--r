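## Euler rotation chain used to place every vertebra from the template.
## Axis convention (package-wide): X mediolateral (+X to the patient's
## left on the PA view), Y anterior-posterior (+Y anterior), Z vertical
## (+Z cranial).  Right-handed.

deg2rad <- function(deg) deg * pi / 180
rad2deg <- function(rad) rad * 180 / pi

#' Elementary rotation matrices
#'
#' Rotations about the three model axes, angles in degrees.  `rot_y()` is
#' the frontal-plane rotation (coronal tilt beta), `rot_x()` the sagittal
#' tilt theta, `rot_z()` the transverse tilt phi.
#'
#' @param deg rotation angle in degrees.
#' @return a 3x3 rotation matrix.
#' @keywords internal
rot_y <- function(deg) {
  a <- deg2rad(deg)
  matrix(c(cos(a), 0, -sin(a),
           0,      1,  0,
           sin(a), 0,  cos(a)), 3, 3)
}

#' @rdname rot_y
#' @keywords internal
rot_x <- function(deg) {
  a <- deg2rad(deg)
  matrix(c(1, 0,      0,
           0, cos(a), sin(a),
           0, -sin(a), cos(a)), 3, 3)
}

#' @rdname rot_y
#' @keywords internal
rot_z <- function(deg) {
  a <- deg2rad(deg)
  matrix(c(cos(a), sin(a), 0,
           -sin(a), cos(a), 0,
           0,      0,      1), 3, 3)
}

#' Composed vertebral rotation (Y-X-Z order)
#'
#' The rotation applied to template coordinates when a vertebra is
#' placed: first the frontal-plane rotation `beta` about Y, then the
#' sagittal tilt `theta` about X, then the transverse tilt `phi` about
#' Z, i.e. `R = Rz(phi) %*% Rx(theta) %*% Ry(beta)`.
#'
#' @param beta_deg,theta_deg,phi_deg rotation angles in degrees.
#' @return a 3x3 rotation matrix.
#' @export
euler_rotation <- function(beta_deg, theta_deg, phi_deg) {
  rot_z(phi_deg) %*% rot_x(theta_deg) %*% rot_y(beta_deg)
}

#' Transform points through the vertebral Euler chain
#'
#' Applies the Y-X-Z rotation chain to a set of points.  The map is a
#' proper rotation: it preserves Euclidean norms and pairwise distances.
#'
#' @param points numeric vector of length 3 or an n x 3 matrix (mm).
#' @param beta_deg frontal-plane (coronal) rotation about Y, degrees.
#' @param theta_deg sagittal tilt about X, degrees.
#' @param phi_deg transverse tilt about Z, degrees.
#' @return transformed coordinates, same shape as `points`.
#' @examples
#' euler_transform(c(10, 20, 30), 0, 0, 0)      # identity
#' euler_transform(c(1, 0, 0), 90, 0, 0)        # -> (0, 0, -1)
#' @export
euler_transform <- function(points, beta_deg, theta_deg, phi_deg) {
  stopifnot(all(is.finite(c(beta_deg, theta_deg, phi_deg))))
  R <- euler_rotation(beta_deg, theta_deg, phi_deg)
  apply_rotation(points, R)
}

#' Inverse of [euler_transform()]
#'
#' Applies the transposed rotation so that
#' `euler_inverse(euler_transform(p, b, t, f), b, t, f)` recovers `p`.
#'
#' @inheritParams euler_transform
#' @return back-transformed coordinates.
#' @export
euler_inverse <- function(points, beta_deg, theta_deg, phi_deg) {
  R <- euler_rotation(beta_deg, theta_deg, phi_deg)
  apply_rotation(points, t(R))
}

apply_rotation <- function(points, R) {
  if (is.matrix(points)) {
    points %*% t(R)
  } else {
    drop(R %*% points)
  }
}

#' Recover Euler angles from a rotation matrix
#'
#' Decomposes `R = Rz(phi) Rx(theta) Ry(beta)` assuming |theta| < 90
#' degrees (always true for vertebral tilts).
#'
#' @param R a 3x3 rotation matrix.
#' @return named numeric vector `c(beta_deg, theta_deg, phi_deg)`.
#' @export
euler_angles_from_rotation <- function(R) {
  theta <- asin(max(-1, min(1, R[3, 2])))
  phi <- atan2(-R[1, 2], R[2, 2])
  beta <- atan2(-R[3, 1], R[3, 3])
  c(beta_deg = rad2deg(beta), theta_deg = rad2deg(theta),
    phi_deg = rad2deg(phi))
}
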