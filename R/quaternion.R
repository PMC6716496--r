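#' Quaternion and rotation utilities
#'
#' Rotations are carried as unit quaternions in wxyz order (scalar first).
#' All helpers are pure and vector-based; trajectories store one quaternion
#' per row of an n x 4 matrix.
#'
#' @name quaternions
NULL

#' Normalize a quaternion to unit length
#' @param q numeric length-4 (wxyz) or n x 4 matrix.
#' @return same shape, unit norm.
#' @export
quat_normalize <- function(q) {
  if (is.matrix(q)) {
    n <- sqrt(rowSums(q^2))
    if (any(n == 0)) stop("zero quaternion cannot be normalized")
    return(q / n)
  }
  n <- sqrt(sum(q^2))
  if (n == 0) stop("zero quaternion cannot be normalized")
  q / n
}

#' Hamilton product of two quaternions
#' @param a,b length-4 wxyz quaternions.
#' @export
quat_multiply <- function(a, b) {
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}

#' Quaternion conjugate (inverse for unit quaternions)
#' @param q length-4 wxyz quaternion.
#' @export
quat_conjugate <- function(q) c(q[1], -q[2], -q[3], -q[4])

#' Convert a unit quaternion to a 3x3 rotation matrix
#' @param q length-4 wxyz unit quaternion.
#' @export
quat_to_matrix <- function(q) {
  q <- quat_normalize(q)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

#' Convert a rotation matrix to a unit quaternion (wxyz)
#'
#' Shepperd's method: picks the numerically largest component first.
#' @param R 3x3 proper rotation matrix.
#' @export
matrix_to_quat <- function(R) {
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
  if (q[1] < 0) q <- -q   # canonical hemisphere: non-negative scalar part
  quat_normalize(q)
}

#' Rotation-vector (axis-angle, radians) to quaternion
#' @param v length-3 rotation vector; its norm is the angle in radians.
#' @export
rotvec_to_quat <- function(v) {
  th <- sqrt(sum(v^2))
  if (th < 1e-12) {
    # first-order expansion keeps the map smooth through zero
    q <- c(1, v / 2)
    return(quat_normalize(q))
  }
  c(cos(th / 2), sin(th / 2) * v / th)
}

#' Quaternion to rotation vector (radians)
#' @param q length-4 wxyz unit quaternion.
#' @export
quat_to_rotvec <- function(q) {
  q <- quat_normalize(q)
  if (q[1] < 0) q <- -q
  s <- sqrt(sum(q[2:4]^2))
  if (s < 1e-12) return(2 * q[2:4])
  th <- 2 * atan2(s, q[1])
  th * q[2:4] / s
}

#' Geodesic angle between two unit quaternions (radians)
#' @param a,b length-4 wxyz unit quaternions.
#' @export
quat_angle <- function(a, b) {
  d <- min(1, abs(sum(a * b)))
  2 * acos(d)
}

#' Spherical linear interpolation between two quaternions
#' @param q0,q1 endpoint unit quaternions (wxyz).
#' @param t interpolation fraction in [0, 1]; vectorized.
#' @return length-4 vector if t is scalar, otherwise length(t) x 4 matrix.
#' @export
quat_slerp <- function(q0, q1, t) {
  q0 <- quat_normalize(q0); q1 <- quat_normalize(q1)
  d <- sum(q0 * q1)
  if (d < 0) { q1 <- -q1; d <- -d }
  if (d > 1 - 1e-10) {
    out <- outer(1 - t, q0) + outer(t, q1)
    out <- quat_normalize(out)
  } else {
    th <- acos(min(1, d))
    out <- (outer(sin((1 - t) * th), q0) + outer(sin(t * th), q1)) / sin(th)
    out <- quat_normalize(out)
  }
  if (length(t) == 1) out[1, ] else out
}

quat_exp <- function(v) {
  # exp of a pure quaternion (0, v)
  th <- sqrt(sum(v^2))
  if (th < 1e-12) return(quat_normalize(c(1, v)))
  c(cos(th), sin(th) * v / th)
}

quat_log <- function(q) {
  # log of a unit quaternion -> pure part
  q <- quat_normalize(q)
  if (q[1] < 0) q <- -q
  s <- sqrt(sum(q[2:4]^2))
  if (s < 1e-12) return(q[2:4])
  atan2(s, q[1]) * q[2:4] / s
}

#' Align a quaternion sequence to one hemisphere
#'
#' Flips signs so consecutive quaternions have non-negative dot product;
#' required before component-wise filtering or spline fitting.
#' @param Q n x 4 matrix of unit quaternions (wxyz).
#' @export
quat_hemisphere_align <- function(Q) {
  if (!is.matrix(Q) || ncol(Q) != 4) stop("Q must be an n x 4 matrix")
  if (nrow(Q) < 2) return(Q)
  for (i in 2:nrow(Q)) {
    if (sum(Q[i, ] * Q[i - 1, ]) < 0) Q[i, ] <- -Q[i, ]
  }
  Q
}
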