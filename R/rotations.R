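# Elementary rotation algebra for the ZXY-fixed joint-angle convention used
# by IMU motion-capture exports: a spherical joint's rotation is composed as
# R = Ry(alpha) %*% Rx(beta) %*% Rz(gamma).
#
# Global frame convention (documented in the vignette): X anteroposterior
# (anterior positive), Y mediolateral, Z vertical up. Flexion/extension is a
# rotation about Y, so a Y-only model produces no mediolateral motion.

#' Elementary rotation matrix about a coordinate axis
#'
#' @param axis One of `"x"`, `"y"`, `"z"` (case-insensitive).
#' @param angle Rotation angle in radians; must be finite.
#'
#' @return A 3x3 orthonormal rotation matrix with determinant +1.
#' @examples
#' rotation_about_axis("y", pi / 2)
#' @export
rotation_about_axis <- function(axis, angle) {
  if (!is.numeric(angle) || length(angle) != 1L || !is.finite(angle))
    stop("'angle' must be a single finite number (radians)")
  axis <- tolower(as.character(axis))
  ca <- cos(angle); sa <- sin(angle)
  switch(axis,
    x = matrix(c(1, 0, 0,   0, ca, sa,   0, -sa, ca), 3L, 3L),
    y = matrix(c(ca, 0, -sa,   0, 1, 0,   sa, 0, ca), 3L, 3L),
    z = matrix(c(ca, sa, 0,   -sa, ca, 0,   0, 0, 1), 3L, 3L),
    stop("'axis' must be one of \"x\", \"y\", \"z\"")
  )
}

#' Joint rotation from an ordered axis sequence
#'
#' Composes the elementary rotations of a joint in the fixed-axis order used
#' throughout the package: a 1-DoF hinge is `Ry(alpha)`, a 2-DoF universal
#' joint `Ry(alpha) Rx(beta)`, and a 3-DoF ball-and-socket joint
#' `Ry(alpha) Rx(beta) Rz(gamma)` (the ZXY-fixed sequence).
#'
#' @param sequence Character vector of axes, e.g. `c("y", "x", "z")`; axes
#'   must be unique.
#' @param angles Numeric vector of angles in radians, one per axis in
#'   `sequence`.
#'
#' @return A 3x3 rotation matrix, the left-to-right product of the
#'   elementary matrices.
#' @export
joint_rotation <- function(sequence, angles) {
  sequence <- tolower(as.character(sequence))
  if (length(sequence) == 0L || anyDuplicated(sequence))
    stop("'sequence' must be a non-empty list of unique axes")
  if (length(angles) != length(sequence))
    stop(sprintf("angle count (%d) does not match DoF sequence length (%d)",
                 length(angles), length(sequence)))
  if (!all(is.finite(angles))) stop("all angles must be finite")
  R <- diag(3)
  for (i in seq_along(sequence))
    R <- R %*% rotation_about_axis(sequence[i], angles[i])
  R
}

#' Decompose a rotation into ZXY-fixed angles
#'
#' Recovers `(alpha, beta, gamma)` such that
#' `R = Ry(alpha) Rx(beta) Rz(gamma)`. Near gimbal lock
#' (`|cos(beta)| < tol`) alpha and gamma are not separable; the returned
#' angles carry a `gimbal` attribute set to `TRUE` and gamma is fixed at 0.
#'
#' @param R A 3x3 rotation matrix.
#' @param tol Gimbal-lock threshold on `|cos(beta)|`.
#' @return Named numeric vector `c(y = alpha, x = beta, z = gamma)` in
#'   radians, with logical attribute `gimbal`.
#' @export
euler_zxy <- function(R, tol = 1e-9) {
  stopifnot(is.matrix(R), all(dim(R) == c(3L, 3L)))
  s_beta <- -R[2L, 3L]
  s_beta <- max(-1, min(1, s_beta))
  beta <- asin(s_beta)
  gimbal <- abs(cos(beta)) < tol
  if (gimbal) {
    # alpha and gamma degenerate into one rotation; attribute all to alpha
    alpha <- atan2(-R[3L, 1L], R[1L, 1L])
    gamma <- 0
  } else {
    alpha <- atan2(R[1L, 3L], R[3L, 3L])
    gamma <- atan2(R[2L, 1L], R[2L, 2L])
  }
  out <- c(y = alpha, x = beta, z = gamma)
  attr(out, "gimbal") <- gimbal
  out
}

# Moore-Penrose pseudoinverse solve via rank-revealing SVD.
# Returns the minimum-norm least-squares solution together with rank and
# conditioning diagnostics. 'tol' is relative to the largest singular value.
pinv_solve <- function(A, b, tol = 1e-10) {
  sv <- svd(A)
  keep <- sv$d > tol * sv$d[1L]
  rank <- sum(keep)
  x <- sv$v[, keep, drop = FALSE] %*%
    ((crossprod(sv$u[, keep, drop = FALSE], b)) / sv$d[keep])
  # columns entangled in the (near-)null space: large loading on a dropped
  # right-singular vector marks the column as unidentifiable
  deficient <- rep(FALSE, ncol(A))
  if (rank < ncol(A)) {
    null_v <- sv$v[, !keep, drop = FALSE]
    deficient <- rowSums(null_v^2) > 1e-8
  }
  list(
    x = drop(x),
    rank = rank,
    n_col = ncol(A),
    condition = if (rank > 0L) sv$d[1L] / sv$d[rank] else Inf,
    singular_values = sv$d,
    deficient = deficient
  )
}
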