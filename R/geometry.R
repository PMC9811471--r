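## Small 3D rotation utilities shared by the camera and calibration code.

#' Rotation matrix from an axis-angle (Rodrigues) vector
#'
#' @param rvec numeric length-3 vector; direction is the rotation axis,
#'   norm is the rotation angle in radians.
#' @return 3x3 rotation matrix.
#' @keywords internal
rotation_from_rvec <- function(rvec) {
  theta <- sqrt(sum(rvec^2))
  if (theta < 1e-12) {
    K <- skew3(rvec)
    return(diag(3) + K)  # first-order, exact enough below 1e-12
  }
  k <- rvec / theta
  K <- skew3(k)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

#' Axis-angle (Rodrigues) vector from a rotation matrix
#'
#' Canonical form: angle in [0, pi]; at angle pi the axis sign is chosen so
#' that the first nonzero component is positive.
#' @param R 3x3 rotation matrix.
#' @return numeric length-3 vector.
#' @keywords internal
rvec_from_rotation <- function(R) {
  ct <- (sum(diag(R)) - 1) / 2
  ct <- min(1, max(-1, ct))
  theta <- acos(ct)
  if (theta < 1e-12) return(c(0, 0, 0))
  if (abs(pi - theta) < 1e-6) {
    ## near pi: axis from the symmetric part
    S <- (R + diag(3)) / 2
    axis <- sqrt(pmax(diag(S), 0))
    ## fix relative signs using off-diagonals
    i <- which.max(axis)
    if (i == 1L) {
      axis[2] <- S[1, 2] / axis[1]; axis[3] <- S[1, 3] / axis[1]
    } else if (i == 2L) {
      axis[1] <- S[1, 2] / axis[2]; axis[3] <- S[2, 3] / axis[2]
    } else {
      axis[1] <- S[1, 3] / axis[3]; axis[2] <- S[2, 3] / axis[3]
    }
    axis <- axis / sqrt(sum(axis^2))
    nz <- which(abs(axis) > 1e-12)[1]
    if (axis[nz] < 0) axis <- -axis
    return(axis * theta)
  }
  axis <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) /
    (2 * sin(theta))
  axis * theta
}

#' Skew-symmetric (cross-product) matrix of a 3-vector
#' @keywords internal
skew3 <- function(v) {
  matrix(c(0, v[3], -v[2],
           -v[3], 0, v[1],
           v[2], -v[1], 0), 3, 3)
}

#' Cross product of two 3-vectors
#' @keywords internal
cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Normalize a vector to unit length
#' @keywords internal
unit3 <- function(v) v / sqrt(sum(v^2))

#' Project a near-rotation onto SO(3) (nearest orthonormal, det +1)
#' @keywords internal
nearest_rotation <- function(M) {
  s <- svd(M)
  R <- s$u %*% t(s$v)
  if (det(R) < 0) R <- s$u %*% diag(c(1, 1, -1)) %*% t(s$v)
  R
}

#' Check that a matrix is a proper rotation
#' @keywords internal
assert_rotation <- function(R, tol = 1e-9, what = "R") {
  if (!is.matrix(R) || !all(dim(R) == c(3, 3)))
    stop(what, " must be a 3x3 matrix", call. = FALSE)
  if (max(abs(t(R) %*% R - diag(3))) > tol || abs(det(R) - 1) > tol)
    stop(what, " must be orthonormal with determinant +1", call. = FALSE)
  invisible(R)
}
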