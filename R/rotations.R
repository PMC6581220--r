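# Quaternion helpers. Quaternions are stored (w, x, y, z), unit norm,
# and act on column vectors as v' = R(q) v.

quat_normalize <- function(q) {
  if (is.matrix(q)) q / sqrt(rowSums(q^2)) else q / sqrt(sum(q^2))
}

quat_identity <- function() c(1, 0, 0, 0)

#' Convert a unit quaternion to a rotation matrix
#' @param q Numeric length-4 quaternion (w, x, y, z).
#' @return 3x3 rotation matrix with determinant +1.
#' @export
quat_to_mat <- function(q) {
  q <- quat_normalize(q)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    nrow = 3, byrow = TRUE)
}

#' Convert a rotation matrix to a unit quaternion
#' @param R 3x3 rotation matrix.
#' @return Length-4 quaternion (w, x, y, z) with w >= 0.
#' @export
mat_to_quat <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] > R[2, 2] && R[1, 1] > R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s, (R[1, 2] + R[2, 1]) / s,
           (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] > R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s, 0.25 * s,
           (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, 0.25 * s)
  }
  q <- quat_normalize(q)
  if (q[1] < 0) q <- -q
  q
}

# Quaternion from axis-angle (axis need not be unit; angle in radians).
quat_from_axis_angle <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  c(cos(angle / 2), sin(angle / 2) * axis)
}

# Vectorised rotation of row-vectors P (n x 3) by per-row quaternions Q
# (n x 4): v' = v + 2 w (u x v) + 2 u x (u x v), u = vector part.
rotate_rows_quat <- function(Q, P) {
  u <- Q[, 2:4, drop = FALSE]
  w <- Q[, 1]
  cross <- function(a, b)
    cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
          a[, 3] * b[, 1] - a[, 1] * b[, 3],
          a[, 1] * b[, 2] - a[, 2] * b[, 1])
  t1 <- cross(u, P)
  P + 2 * w * t1 + 2 * cross(u, t1)
}

# Vectorised slerp between row-quaternion matrices Q1, Q2 with weights
# alpha in [0, 1]. Antipodal pairs are flipped to the short arc.
quat_slerp_rows <- function(Q1, Q2, alpha) {
  d <- rowSums(Q1 * Q2)
  flip <- d < 0
  Q2[flip, ] <- -Q2[flip, , drop = FALSE]
  d <- abs(d)
  d <- pmin(d, 1)
  th <- acos(d)
  sth <- sin(th)
  small <- sth < 1e-8
  w1 <- ifelse(small, 1 - alpha, sin((1 - alpha) * th) / sth)
  w2 <- ifelse(small, alpha, sin(alpha * th) / sth)
  quat_normalize(w1 * Q1 + w2 * Q2)
}

# Angle (radians) of the relative rotation between two quaternions.
quat_angle_between <- function(q1, q2) {
  d <- min(1, abs(sum(q1 * q2)))
  2 * acos(d)
}
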