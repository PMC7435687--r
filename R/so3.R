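#' Standard gravity
#'
#' Magnitude of standard gravitational acceleration used throughout the
#' package for unit conversion (1 g) and for the gravity vector in strapdown
#' integration.  The global frame is z-up, so the gravity vector is
#' `c(0, 0, -GRAVITY)`.
#'
#' @format A length-1 numeric, 9.80665 m/s^2.
#' @export
GRAVITY <- 9.80665

# gravity vector in the global (z-up) frame
gravity_vec <- function() c(0, 0, -GRAVITY)

#' Skew-symmetric (cross-product) matrix of a 3-vector
#'
#' Returns the matrix `B` such that `B %*% x == cross(v, x)`.
#'
#' @param v numeric length-3 vector.
#' @return 3x3 skew-symmetric matrix.
#' @export
skew <- function(v) {
  stopifnot(length(v) == 3)
  matrix(c(0, v[3], -v[2],
           -v[3], 0, v[1],
           v[2], -v[1], 0), 3, 3)
}

#' Rotation matrix from a rotation vector (exponential map on SO(3))
#'
#' Rodrigues' formula `I + sin(s)/s B + (1 - cos(s))/s^2 B^2` with
#' `s = |v|` and `B = skew(v)`.  For small angles the trigonometric
#' coefficients are replaced by their series expansions
#' `sin(s)/s ~ 1 - s^2/6` and `(1-cos(s))/s^2 ~ 1/2 - s^2/24` to avoid
#' cancellation.
#'
#' @param v rotation vector (axis * angle), radians.
#' @return 3x3 rotation matrix.
#' @export
rotvec_to_matrix <- function(v) {
  s <- sqrt(sum(v^2))
  B <- skew(v)
  if (s < 1e-8) {
    c1 <- 1 - s^2 / 6
    c2 <- 0.5 - s^2 / 24
  } else {
    c1 <- sin(s) / s
    c2 <- (1 - cos(s)) / s^2
  }
  diag(3) + c1 * B + c2 * (B %*% B)
}

#' Rotation vector from a rotation matrix (logarithm map on SO(3))
#'
#' Inverse of [rotvec_to_matrix()].  Stable for angles near 0 and near pi.
#'
#' @param R 3x3 rotation matrix.
#' @return numeric length-3 rotation vector, radians.
#' @export
matrix_to_rotvec <- function(R) {
  ca <- (sum(diag(R)) - 1) / 2
  ca <- min(1, max(-1, ca))
  angle <- acos(ca)
  if (angle < 1e-10) {
    # first-order: R ~ I + skew(v)
    return(c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) / 2)
  }
  if (angle > pi - 1e-2) {
    # near pi the antisymmetric part nearly vanishes and acos loses
    # precision.  The symmetrized matrix M = (R + R')/2 + I equals
    # (1 + cos a) I + (1 - cos a) u u', whose dominant eigenvector is the
    # axis; two power steps reduce the axis error to machine level.  The
    # angle comes from sin(a) = |antisymmetric part| / 2.
    M <- (R + t(R)) / 2 + diag(3)
    axis <- M[, which.max(diag(M))]
    for (k in 1:2) {
      axis <- as.numeric(M %*% axis)
      axis <- axis / sqrt(sum(axis^2))
    }
    w <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
    angle <- pi - asin(min(1, sqrt(sum(w^2)) / 2))
    if (sum(w * axis) < 0) axis <- -axis
    return(axis * angle)
  }
  v <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
  v * angle / (2 * sin(angle))
}

# Nearest rotation matrix (polar factor via SVD); used to keep attitude
# estimates on SO(3) after multiplicative corrections.
orthonormalize <- function(R) {
  sv <- svd(R)
  U <- sv$u
  V <- sv$v
  D <- diag(c(1, 1, sign(det(U %*% t(V)))))
  U %*% D %*% t(V)
}

# One Newton step of the polar iteration, enough to remove the ~1e-16
# per-step drift of chained rotation products without an SVD.
renormalize_rotation <- function(R) {
  R %*% (1.5 * diag(3) - 0.5 * crossprod(R)) # R (3I - R'R)/2
}

# yaw (heading) angle of the body x-axis projected on the horizontal plane
yaw_of <- function(R) atan2(R[2, 1], R[1, 1])

# rotation about the global z axis
rot_z <- function(psi) {
  matrix(c(cos(psi), sin(psi), 0,
           -sin(psi), cos(psi), 0,
           0, 0, 1), 3, 3, byrow = FALSE)
}

# rotation about the global y axis (used for foot pitch)
rot_y <- function(th) {
  matrix(c(cos(th), 0, -sin(th),
           0, 1, 0,
           sin(th), 0, cos(th)), 3, 3, byrow = FALSE)
}
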