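#' Quaternion and rotation algebra
#'
#' Rotations are carried as scalar-first unit quaternions `c(w, x, y, z)`
#' acting as local-frame to world-frame maps: `v_world = R(q) %*% v_local`.
#' The double cover (q and -q encode the same rotation) is resolved by
#' [quat_canonicalize()], which every user-facing operation applies before
#' returning a quaternion.
#'
#' @name quaternion-algebra
#' @keywords internal
NULL

.QUAT_TOL <- 1e-9

#' Canonicalize a quaternion
#'
#' Normalizes a 4-vector to unit length and resolves the antipodal
#' ambiguity: the returned quaternion has `w >= 0`; when `w` is zero
#' (a 180 degree rotation) the sign is fixed so the first nonzero vector
#' component is positive.
#'
#' @param q Numeric length-4 vector `(w, x, y, z)`, scalar first. Need not
#'   be unit length, but must have nonzero norm.
#' @return Unit quaternion `(w, x, y, z)` with `w >= 0`.
#' @examples
#' quat_canonicalize(c(2, 0, 0, 0))            # scaled identity -> identity
#' quat_canonicalize(c(-0.5, 0.5, -0.5, 0.5))  # antipode flipped to w >= 0
#' @export
quat_canonicalize <- function(q) {
  q <- as.numeric(q)
  stopifnot(length(q) == 4L)
  if (!all(is.finite(q))) stop("invalid rotation: non-finite quaternion components")
  nrm <- sqrt(sum(q^2))
  if (nrm < .QUAT_TOL) stop("invalid rotation: zero-norm quaternion")
  q <- q / nrm
  if (q[1] < 0) {
    q <- -q
  } else if (q[1] == 0) {
    # w = 0: pick the hemisphere where the first nonzero vector component > 0
    nz <- which(q[2:4] != 0)
    if (length(nz) > 0 && q[1 + nz[1]] < 0) q <- -q
  }
  unname(q)
}

quat_is_unit <- function(q, tol = .QUAT_TOL) {
  abs(sqrt(sum(q^2)) - 1) <= tol
}

#' Hamilton product of two quaternions
#' @param a,b Quaternions `(w, x, y, z)`.
#' @return The product `a %*% b` as a quaternion (not canonicalized).
#' @keywords internal
quat_multiply <- function(a, b) {
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}

#' @rdname quat_multiply
#' @keywords internal
quat_conjugate <- function(q) c(q[1], -q[2], -q[3], -q[4])

#' Relative orientation between two poses
#'
#' Returns the canonicalized rotation taking the local frame of `q_a` onto
#' the local frame of `q_b`, i.e. `q_a^-1 (x) q_b`. The relative orientation
#' of a pose with itself is the identity.
#'
#' @param q_a,q_b Unit quaternions.
#' @return Canonical unit quaternion.
#' @export
relative_orientation <- function(q_a, q_b) {
  stopifnot(quat_is_unit(q_a), quat_is_unit(q_b))
  quat_canonicalize(quat_multiply(quat_conjugate(q_a), q_b))
}

#' Rotation matrix of a unit quaternion
#' @param q Unit quaternion `(w, x, y, z)`.
#' @return 3x3 proper rotation matrix.
#' @export
quat_to_matrix <- function(q) {
  stopifnot(quat_is_unit(q))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

#' Unit quaternion of a proper rotation matrix
#'
#' Shepperd's method: the largest of the four candidate denominators is
#' used, so the conversion is stable for all rotations.
#'
#' @param R 3x3 proper rotation matrix (`det(R) = +1`).
#' @return Canonical unit quaternion.
#' @export
matrix_to_quat <- function(R) {
  stopifnot(is.matrix(R), all(dim(R) == c(3L, 3L)))
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s,
           (R[3, 2] - R[2, 3]) / s,
           (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] > R[2, 2] && R[1, 1] > R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s,
           0.25 * s,
           (R[1, 2] + R[2, 1]) / s,
           (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] > R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s,
           (R[1, 2] + R[2, 1]) / s,
           0.25 * s,
           (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s,
           (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s,
           0.25 * s)
  }
  quat_canonicalize(q)
}

#' Rotate a vector (or point matrix) by a unit quaternion
#'
#' @param q Unit quaternion.
#' @param v Numeric length-3 vector, or an n x 3 matrix of row vectors.
#' @return Rotated vector/matrix, same shape as `v`.
#' @export
rotate_vector <- function(q, v) {
  R <- quat_to_matrix(q)
  if (is.matrix(v)) {
    v %*% t(R)
  } else {
    as.numeric(R %*% v)
  }
}

#' Geodesic angle between two rotations
#'
#' Antipode-invariant rotation angle `2 * acos(|<q_a, q_b>|)`.
#'
#' @param q_a,q_b Unit quaternions.
#' @return Angle in degrees, in `[0, 180]`.
#' @export
quat_angle <- function(q_a, q_b) {
  stopifnot(quat_is_unit(q_a), quat_is_unit(q_b))
  d <- min(abs(sum(q_a * q_b)), 1)
  2 * acos(d) * 180 / pi
}

#' Chordal mean of unit quaternions
#'
#' Sign-aligns all quaternions to the first, accumulates the sum of outer
#' products, and returns the dominant eigenvector -- the rotation minimizing
#' the summed squared chordal distance, antipode-invariant by construction.
#'
#' @param qs List of unit quaternions, or an n x 4 matrix (rows scalar-first).
#' @return Canonical unit quaternion.
#' @export
quat_mean <- function(qs) {
  if (is.matrix(qs)) qs <- asplit(qs, 1)
  if (length(qs) == 0L) stop("empty input: no quaternions to average")
  M <- matrix(0, 4, 4)
  q1 <- as.numeric(qs[[1]])
  for (q in qs) {
    q <- as.numeric(q)
    stopifnot(quat_is_unit(q))
    if (sum(q * q1) < 0) q <- -q
    M <- M + tcrossprod(q)
  }
  e <- eigen(M, symmetric = TRUE)
  if (length(qs) > 1 && (e$values[1] - e$values[2]) < .QUAT_TOL * max(e$values[1], 1)) {
    stop("degenerate mean: leading eigenvalues tie, orientation average undefined")
  }
  quat_canonicalize(e$vectors[, 1])
}

#' Quaternion for a rotation about an axis
#' @param axis Numeric length-3 rotation axis (normalized internally).
#' @param angle_deg Rotation angle in degrees (right-handed about `axis`).
#' @return Canonical unit quaternion.
#' @export
quat_from_axis_angle <- function(axis, angle_deg) {
  axis <- as.numeric(axis)
  n <- sqrt(sum(axis^2))
  if (n == 0) stop("invalid rotation: zero axis")
  half <- angle_deg * pi / 360
  quat_canonicalize(c(cos(half), sin(half) * axis / n))
}

#' ZYZ intrinsic Euler angles to quaternion
#'
#' The (rot, tilt, psi) convention used in subtomogram-averaging metadata:
#' an intrinsic rotation about z by `rot`, then about the new y by `tilt`,
#' then about the new z by `psi`; `(0, 0, 0)` is the identity.
#'
#' @param rot,tilt,psi Angles in degrees.
#' @return Canonical unit quaternion.
#' @export
euler_zyz_to_quat <- function(rot, tilt, psi) {
  q <- quat_multiply(
    quat_multiply(quat_from_axis_angle(c(0, 0, 1), rot),
                  quat_from_axis_angle(c(0, 1, 0), tilt)),
    quat_from_axis_angle(c(0, 0, 1), psi))
  quat_canonicalize(q)
}

#' Quaternion to ZYZ intrinsic Euler angles
#'
#' Inverse of [euler_zyz_to_quat()]. On the gimbal-degenerate manifold
#' (tilt 0 or 180 degrees) `rot` is set to 0 and the full in-plane angle is
#' carried by `psi`.
#'
#' @param q Unit quaternion.
#' @return Named numeric vector `(rot, tilt, psi)` in degrees.
#' @export
quat_to_euler_zyz <- function(q) {
  R <- quat_to_matrix(q)
  tilt <- acos(min(max(R[3, 3], -1), 1))
  if (sin(tilt) > 1e-9) {
    rot <- atan2(R[2, 3], R[1, 3])
    psi <- atan2(R[3, 2], -R[3, 1])
  } else {
    rot <- 0
    psi <- atan2(R[2, 1], R[1, 1]) * sign(R[3, 3])
  }
  c(rot = rot, tilt = tilt, psi = psi) * 180 / pi
}

#' Uniformly random unit quaternions
#' @param n Number of draws.
#' @return n x 4 matrix of canonical unit quaternions (rows).
#' @export
random_quaternions <- function(n) {
  m <- matrix(stats::rnorm(4 * n), ncol = 4)
  t(apply(m, 1, quat_canonicalize))
}

#' Small random perturbation of a rotation
#'
#' Composes `q` with a rotation about a uniformly random axis by an angle
#' drawn uniformly in `[0, max_angle_deg]`.
#'
#' @param q Unit quaternion.
#' @param max_angle_deg Maximum perturbation angle (degrees).
#' @return Canonical unit quaternion.
#' @export
quat_perturb <- function(q, max_angle_deg) {
  ax <- stats::rnorm(3)
  ang <- stats::runif(1, 0, max_angle_deg)
  quat_canonicalize(quat_multiply(q, quat_from_axis_angle(ax, ang)))
}
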