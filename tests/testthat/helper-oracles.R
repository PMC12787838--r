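# Independent brute-force oracles, deliberately written with explicit loops
# and the textbook formulas, never sharing code with the package internals.

oracle_anova_oneway <- function(m) {
  n <- nrow(m); k <- ncol(m)
  grand <- sum(m) / (n * k)
  ssb <- 0
  for (i in seq_len(n)) {
    rmean <- sum(m[i, ]) / k
    ssb <- ssb + k * (rmean - grand)^2
  }
  ssw <- 0
  for (i in seq_len(n)) for (j in seq_len(k)) {
    rmean <- sum(m[i, ]) / k
    ssw <- ssw + (m[i, j] - rmean)^2
  }
  list(ms_between = ssb / (n - 1), ms_within = ssw / (n * (k - 1)))
}

oracle_alpha <- function(m) {
  k <- ncol(m)
  item_var <- 0
  for (j in seq_len(k)) item_var <- item_var + stats::var(m[, j])
  total <- numeric(nrow(m))
  for (i in seq_len(nrow(m))) total[i] <- sum(m[i, ])
  k / (k - 1) * (1 - item_var / stats::var(total))
}

oracle_icc <- function(m) {
  a <- oracle_anova_oneway(m)
  k <- ncol(m)
  (a$ms_between - a$ms_within) / (a$ms_between + (k - 1) * a$ms_within)
}

oracle_cohens_d <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp <- sqrt(((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) /
               (nx + ny - 2))
  (mean(x) - mean(y)) / sp
}

# closed-form orientation for a piecewise-constant rate stream: product of
# one axis-angle quaternion per sampling interval, in order
oracle_quat_product <- function(gyro_dps, dt) {
  n <- nrow(gyro_dps)
  out <- matrix(0, n, 4L)
  q <- c(1, 0, 0, 0)
  out[1L, ] <- q
  for (k in seq_len(n - 1L)) {
    rv <- gyro_dps[k, ] * pi / 180 * dt
    ang <- sqrt(sum(rv^2))
    dq <- if (ang == 0) c(1, 0, 0, 0) else c(cos(ang / 2), sin(ang / 2) * rv / ang)
    q <- c(
      q[1] * dq[1] - q[2] * dq[2] - q[3] * dq[3] - q[4] * dq[4],
      q[1] * dq[2] + q[2] * dq[1] + q[3] * dq[4] - q[4] * dq[3],
      q[1] * dq[3] - q[2] * dq[4] + q[3] * dq[1] + q[4] * dq[2],
      q[1] * dq[4] + q[2] * dq[3] - q[3] * dq[2] + q[4] * dq[1]
    )
    out[k + 1L, ] <- q
  }
  out
}

quat_angle_deg <- function(a, b) {
  d <- abs(sum(a * b))
  2 * acos(min(1, d)) * 180 / pi
}
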