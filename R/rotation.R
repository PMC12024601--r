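#' Convert an axis-angle rotation vector to a rotation matrix
#'
#' Implements the Rodrigues formula. The direction of `rvec` is the rotation
#' axis and its Euclidean norm the rotation angle in radians. The zero vector
#' maps to the identity.
#'
#' @param rvec numeric length-3 axis-angle vector (radians).
#' @return 3x3 orthonormal rotation matrix with determinant +1.
#' @seealso [matrix_to_rodrigues()] for the inverse mapping.
#' @export
#' @examples
#' rodrigues_to_matrix(c(0, 0, pi / 2)) %*% c(1, 0, 0)  # maps x to y
rodrigues_to_matrix <- function(rvec) {
  rvec <- as.numeric(rvec)
  stopifnot(length(rvec) == 3L, all(is.finite(rvec)))
  theta <- sqrt(sum(rvec^2))
  if (theta < .Machine$double.eps^0.75) {
    # second-order small-angle expansion keeps the map smooth at zero
    K <- skew(rvec)
    return(diag(3) + K + 0.5 * (K %*% K))
  }
  k <- rvec / theta
  K <- skew(k)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

#' Convert a rotation matrix to an axis-angle rotation vector
#'
#' Inverse of [rodrigues_to_matrix()] with the angle normalized to
#' `[0, pi]`; the round trip recovers the matrix exactly but recovers the
#' vector only up to the usual 2*pi ambiguity.
#'
#' @param R 3x3 rotation matrix (orthonormal, det +1).
#' @return numeric length-3 axis-angle vector (radians).
#' @export
matrix_to_rodrigues <- function(R) {
  check_rotation_matrix(R)
  cos_theta <- max(-1, min(1, (sum(diag(R)) - 1) / 2))
  theta <- acos(cos_theta)
  if (theta < 1e-12) {
    return(c(0, 0, 0))
  }
  if (abs(pi - theta) < 1e-6) {
    # near pi the antisymmetric part vanishes; take axis from R + I
    B <- (R + diag(3)) / 2
    axis <- sqrt(pmax(diag(B), 0))
    # fix signs from the largest component
    i <- which.max(axis)
    s <- sign(B[i, ])
    s[s == 0] <- 1
    axis <- axis * s / s[i]
    axis <- axis / sqrt(sum(axis^2))
    return(axis * theta)
  }
  axis <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) /
    (2 * sin(theta))
  axis * theta
}

#' Decompose a rotation matrix into pitch, yaw and roll
#'
#' Uses the intrinsic x-y-z convention: `R = Rx(pitch) %*% Ry(yaw) %*%
#' Rz(roll)`. Pitch is the rotation about the lateral (x) axis and is the
#' component that drives the neck grade in the scoring pipeline.
#'
#' Near gimbal lock (`|cos(yaw)| < 1e-9`) roll is set to 0 by convention and
#' the result carries attribute `gimbal_lock = TRUE`.
#'
#' @param R 3x3 rotation matrix.
#' @return named numeric vector `c(pitch, yaw, roll)` in degrees.
#' @export
euler_from_matrix <- function(R) {
  check_rotation_matrix(R)
  sy <- max(-1, min(1, R[1, 3]))
  yaw <- asin(sy)
  gimbal <- abs(cos(yaw)) < 1e-9
  if (gimbal) {
    roll <- 0
    pitch <- atan2(R[2, 1], R[2, 2])
  } else {
    pitch <- atan2(-R[2, 3], R[3, 3])
    roll <- atan2(-R[1, 2], R[1, 1])
  }
  out <- c(pitch = pitch, yaw = yaw, roll = roll) * 180 / pi
  attr(out, "gimbal_lock") <- gimbal
  out
}

#' Compose a rotation matrix from pitch, yaw and roll
#'
#' Inverse of [euler_from_matrix()] under the same intrinsic x-y-z order.
#'
#' @param pitch,yaw,roll angles in degrees.
#' @return 3x3 rotation matrix.
#' @export
euler_to_matrix <- function(pitch, yaw, roll) {
  rot_x(pitch * pi / 180) %*% rot_y(yaw * pi / 180) %*% rot_z(roll * pi / 180)
}

skew <- function(v) {
  matrix(c(0, v[3], -v[2],
           -v[3], 0, v[1],
           v[2], -v[1], 0), 3, 3)
}

rot_x <- function(a) matrix(c(1, 0, 0,
                              0, cos(a), sin(a),
                              0, -sin(a), cos(a)), 3, 3)
rot_y <- function(a) matrix(c(cos(a), 0, -sin(a),
                              0, 1, 0,
                              sin(a), 0, cos(a)), 3, 3)
rot_z <- function(a) matrix(c(cos(a), sin(a), 0,
                              -sin(a), cos(a), 0,
                              0, 0, 1), 3, 3)

check_rotation_matrix <- function(R, tol = 1e-6) {
  if (!is.matrix(R) || any(dim(R) != 3L) || !all(is.finite(R))) {
    stop("`R` must be a finite 3x3 matrix", call. = FALSE)
  }
  if (max(abs(crossprod(R) - diag(3))) > tol || abs(det(R) - 1) > tol) {
    stop("`R` is not a proper rotation matrix (orthonormal, det +1)",
         call. = FALSE)
  }
  invisible(R)
}
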