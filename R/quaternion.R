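# Quaternion utilities used by the strap-down integrator and the simulator.
# Convention: q = c(w, x, y, z), unit norm, maps body -> world: v_w = R(q) v_b.
# Euler angles are intrinsic Z-Y'-X'' (yaw, pitch, roll), degrees, in (-180, 180].
# Plane mapping for a segment-aligned sensor: sagittal = pitch, frontal = roll,
# transverse = yaw.

quat_normalize <- function(q) {
  n <- sqrt(sum(q * q))
  if (n < .Machine$double.eps) stop("cannot normalize a zero quaternion")
  q / n
}

quat_conjugate <- function(q) c(q[1L], -q[2L], -q[3L], -q[4L])

quat_multiply <- function(a, b) {
  c(
    a[1L] * b[1L] - a[2L] * b[2L] - a[3L] * b[3L] - a[4L] * b[4L],
    a[1L] * b[2L] + a[2L] * b[1L] + a[3L] * b[4L] - a[4L] * b[3L],
    a[1L] * b[3L] - a[2L] * b[4L] + a[3L] * b[1L] + a[4L] * b[2L],
    a[1L] * b[4L] + a[2L] * b[3L] - a[3L] * b[2L] + a[4L] * b[1L]
  )
}

# Rotation about `axis` (3-vector, need not be unit) by `angle_rad`.
quat_from_axis_angle <- function(axis, angle_rad) {
  n <- sqrt(sum(axis * axis))
  if (n < .Machine$double.eps || angle_rad == 0) return(c(1, 0, 0, 0))
  u <- axis / n
  h <- angle_rad / 2
  c(cos(h), sin(h) * u)
}

# Exponential map of a rotation vector (axis * angle, radians).
quat_exp_rotvec <- function(rv) {
  ang <- sqrt(sum(rv * rv))
  if (ang < 1e-300) return(c(1, 0, 0, 0))
  quat_from_axis_angle(rv, ang)
}

# Rotate a body-frame vector into the world frame.
quat_rotate <- function(q, v) {
  qv <- c(0, v)
  out <- quat_multiply(quat_multiply(q, qv), quat_conjugate(q))
  out[2:4]
}

quat_rotate_inverse <- function(q, v) quat_rotate(quat_conjugate(q), v)

# Angular separation between two orientations, degrees.
quat_angle_between <- function(a, b) {
  d <- quat_multiply(quat_conjugate(a), b)
  w <- min(1, abs(d[1L]))
  2 * acos(w) * 180 / pi
}

# yaw, pitch, roll (deg) -> quaternion, intrinsic Z-Y'-X''.
quat_from_euler <- function(yaw_deg, pitch_deg, roll_deg) {
  y <- yaw_deg * pi / 360
  p <- pitch_deg * pi / 360
  r <- roll_deg * pi / 360
  cy <- cos(y); sy <- sin(y)
  cp <- cos(p); sp <- sin(p)
  cr <- cos(r); sr <- sin(r)
  c(
    cy * cp * cr + sy * sp * sr,
    cy * cp * sr - sy * sp * cr,
    cy * sp * cr + sy * cp * sr,
    sy * cp * cr - cy * sp * sr
  )
}

# quaternion -> c(roll, pitch, yaw) in degrees.
quat_to_euler <- function(q) {
  w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
  sinp <- 2 * (w * y - x * z)
  sinp <- max(-1, min(1, sinp))
  roll <- atan2(2 * (w * x + y * z), 1 - 2 * (x * x + y * y))
  pitch <- asin(sinp)
  yaw <- atan2(2 * (w * z + x * y), 1 - 2 * (y * y + z * z))
  c(roll = roll, pitch = pitch, yaw = yaw) * 180 / pi
}

# Vectorised Euler extraction from an n x 4 quaternion matrix.
quat_to_euler_matrix <- function(qm) {
  w <- qm[, 1L]; x <- qm[, 2L]; y <- qm[, 3L]; z <- qm[, 4L]
  sinp <- pmax(-1, pmin(1, 2 * (w * y - x * z)))
  cbind(
    roll = atan2(2 * (w * x + y * z), 1 - 2 * (x * x + y * y)),
    pitch = asin(sinp),
    yaw = atan2(2 * (w * z + x * y), 1 - 2 * (y * y + z * z))
  ) * 180 / pi
}

# Mean orientation of a tight cluster of quaternions: sign-aligned
# component-wise mean, renormalized. Adequate for a 5-s standing window.
quat_mean <- function(qm) {
  if (is.null(dim(qm))) return(quat_normalize(qm))
  ref <- qm[1L, ]
  s <- sign(qm %*% ref)
  s[s == 0] <- 1
  quat_normalize(colSums(qm * as.vector(s)))
}
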