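# Rotation utilities shared by the docking sampler, the MC engine and the
# trajectory generators. Matrices are used internally; trajectories store
# unit quaternions (scalar-first, w >= 0).

#' Rotation matrix from Euler angles (z-y-z convention)
#'
#' @param alpha,beta,gamma Angles in radians.
#' @return Orthonormal 3x3 matrix with determinant +1.
#' @export
euler_zyz <- function(alpha, beta, gamma) {
  rz <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
  ry <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
  rz(alpha) %*% ry(beta) %*% rz(gamma)
}

# Rotation about an arbitrary unit axis by angle theta (radians).
axis_angle_matrix <- function(axis, theta) {
  axis <- axis / sqrt(sum(axis^2))
  ct <- cos(theta); st <- sin(theta); vt <- 1 - ct
  x <- axis[1]; y <- axis[2]; z <- axis[3]
  matrix(c(
    ct + x * x * vt, x * y * vt + z * st, x * z * vt - y * st,
    x * y * vt - z * st, ct + y * y * vt, y * z * vt + x * st,
    x * z * vt + y * st, y * z * vt - x * st, ct + z * z * vt
  ), 3, 3)
}

#' Convert a rotation matrix to a unit quaternion
#'
#' Scalar-first (w, x, y, z) with w >= 0.
#'
#' @param m Orthonormal 3x3 rotation matrix.
#' @return Numeric 4-vector of unit norm.
#' @export
matrix_to_quaternion <- function(m) {
  tr <- m[1, 1] + m[2, 2] + m[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (m[3, 2] - m[2, 3]) / s, (m[1, 3] - m[3, 1]) / s,
           (m[2, 1] - m[1, 2]) / s)
  } else if (m[1, 1] >= m[2, 2] && m[1, 1] >= m[3, 3]) {
    s <- sqrt(1 + m[1, 1] - m[2, 2] - m[3, 3]) * 2
    q <- c((m[3, 2] - m[2, 3]) / s, 0.25 * s, (m[1, 2] + m[2, 1]) / s,
           (m[1, 3] + m[3, 1]) / s)
  } else if (m[2, 2] >= m[3, 3]) {
    s <- sqrt(1 + m[2, 2] - m[1, 1] - m[3, 3]) * 2
    q <- c((m[1, 3] - m[3, 1]) / s, (m[1, 2] + m[2, 1]) / s, 0.25 * s,
           (m[2, 3] + m[3, 2]) / s)
  } else {
    s <- sqrt(1 + m[3, 3] - m[1, 1] - m[2, 2]) * 2
    q <- c((m[2, 1] - m[1, 2]) / s, (m[1, 3] + m[3, 1]) / s,
           (m[2, 3] + m[3, 2]) / s, 0.25 * s)
  }
  q <- q / sqrt(sum(q^2))
  if (q[1] < 0) q <- -q
  q
}

#' Convert a unit quaternion to a rotation matrix
#'
#' @param q Numeric 4-vector (w, x, y, z).
#' @return Orthonormal 3x3 rotation matrix.
#' @export
quaternion_to_matrix <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y * y + z * z), 2 * (x * y + w * z), 2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x * x + z * z), 2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x * x + y * y)
  ), 3, 3)
}

# Hamilton product q1 * q2 on n x 4 matrices (vectorized over rows).
quaternion_multiply <- function(q1, q2) {
  if (is.null(dim(q1))) q1 <- matrix(q1, 1, 4)
  if (is.null(dim(q2))) q2 <- matrix(q2, 1, 4)
  w1 <- q1[, 1]; x1 <- q1[, 2]; y1 <- q1[, 3]; z1 <- q1[, 4]
  w2 <- q2[, 1]; x2 <- q2[, 2]; y2 <- q2[, 3]; z2 <- q2[, 4]
  cbind(
    w1 * w2 - x1 * x2 - y1 * y2 - z1 * z2,
    w1 * x2 + x1 * w2 + y1 * z2 - z1 * y2,
    w1 * y2 - x1 * z2 + y1 * w2 + z1 * x2,
    w1 * z2 + x1 * y2 - y1 * x2 + z1 * w2
  )
}

# Rotate one fixed vector v by many quaternions (rows of q); returns n x 3.
quaternion_rotate_vector <- function(q, v) {
  w <- q[, 1]; x <- q[, 2]; y <- q[, 3]; z <- q[, 4]
  # t = 2 q_v x v ; v' = v + w t + q_v x t
  tx <- 2 * (y * v[3] - z * v[2])
  ty <- 2 * (z * v[1] - x * v[3])
  tz <- 2 * (x * v[2] - y * v[1])
  cbind(
    v[1] + w * tx + (y * tz - z * ty),
    v[2] + w * ty + (z * tx - x * tz),
    v[3] + w * tz + (x * ty - y * tx)
  )
}

# Uniform random rotation as a quaternion (4 normals, normalized, w >= 0).
random_quaternion <- function(n = 1) {
  q <- matrix(stats::rnorm(4 * n), n, 4)
  q <- q / sqrt(rowSums(q^2))
  flip <- q[, 1] < 0
  q[flip, ] <- -q[flip, , drop = FALSE]
  q
}

# Random uniform unit vectors, n x 3.
random_unit_vectors <- function(n) {
  v <- matrix(stats::rnorm(3 * n), n, 3)
  v / sqrt(rowSums(v^2))
}
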