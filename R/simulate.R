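#' Configuration of a simulated six-minute walk session
#'
#' The simulator generates kinematically consistent angle trajectories for
#' the two shanks and the sacrum and the 9-DOF sensor signals they imply.
#' Per stride, the shank sagittal angle follows a smooth two-harmonic
#' template scaled to the configured range of motion, with its maximum (the
#' velocity zero crossing after mid-swing) at initial contact; pelvic yaw
#' oscillates at stride frequency with its positive excursion at left
#' contact; pelvic tilt stays at `pelvic_tilt_deg` plus a small
#' step-frequency oscillation. Whenever the cumulative distance crosses a
#' course length, a smooth 2-s 180-degree heading ramp (a turn) is inserted;
#' cadence is held constant throughout so the ground-truth step count stays
#' consistent with cadence x duration. The walk is bracketed by static
#' standing intervals (`lead_s` includes the 5-s calibration).
#'
#' @param cadence_spm cadence in steps per minute.
#' @param step_length_m step length, meters.
#' @param duration_s walking duration, seconds (360 = the 6MWT).
#' @param course a [course_model()].
#' @param shank_sagittal_rom_deg peak-to-peak sagittal shank excursion.
#' @param pelvic_tilt_deg mean sacrum sagittal angle (not zeroed by
#'   calibration).
#' @param pelvic_yaw_amp_deg pelvic axial-rotation amplitude.
#' @param pelvic_tilt_osc_deg,pelvic_roll_amp_deg secondary pelvis
#'   oscillation amplitudes.
#' @param shank_frontal_amp_deg,shank_transverse_amp_deg secondary shank
#'   oscillation amplitudes.
#' @param asymmetry length-2 vector of per-limb ROM scale factors.
#' @param noise_sd named vector `c(acc_g=, gyro_dps=, mag_gauss=)` of
#'   per-channel Gaussian noise SDs.
#' @param gyro_bias_dps 3-vector constant gyroscope bias, deg/s (same bias
#'   on all three sensors).
#' @param acc_bob_g amplitude of the stride-periodic vertical specific-force
#'   component, g.
#' @param lead_s,tail_s static standing before/after the walk, seconds.
#' @param rate_hz sampling rate.
#' @param seed integer seed; identical seeds give bit-identical sessions.
#' @return a `gait_sim_config` list.
#' @export
gait_sim_config <- function(cadence_spm = 595 / 6, step_length_m = 0.6,
                            duration_s = 360, course = course_model(),
                            shank_sagittal_rom_deg = 20,
                            pelvic_tilt_deg = 21.5, pelvic_yaw_amp_deg = 5,
                            pelvic_tilt_osc_deg = 0.8,
                            pelvic_roll_amp_deg = 1,
                            shank_frontal_amp_deg = 2,
                            shank_transverse_amp_deg = 3,
                            asymmetry = c(left = 1, right = 1),
                            noise_sd = c(acc_g = 0, gyro_dps = 0, mag_gauss = 0),
                            gyro_bias_dps = c(0, 0, 0), acc_bob_g = 0.02,
                            lead_s = 10, tail_s = 5, rate_hz = 60, seed = 1) {
  if (cadence_spm <= 0 || step_length_m <= 0 || duration_s <= 0)
    stop("config error: cadence, step length and duration must be positive")
  if (any(noise_sd < 0)) stop("config error: noise SDs must be >= 0")
  structure(as.list(environment()), class = "gait_sim_config")
}

smoothstep <- function(u) {
  u <- pmax(0, pmin(1, u))
  u * u * (3 - 2 * u)
}
smoothstep_deriv <- function(u) {
  inside <- u > 0 & u < 1
  ifelse(inside, 6 * u * (1 - u), 0)
}

# Two-harmonic stride template (degrees) and its phase derivative.
# Velocity has exactly two zero crossings per stride: negative-going at
# integer phase (initial contact, angle maximum) and positive-going at
# half phase.
stride_template <- function(phi, a1, a2) a1 * cos(2 * pi * phi) + a2 * cos(4 * pi * phi)
stride_template_dphi <- function(phi, a1, a2)
  -2 * pi * a1 * sin(2 * pi * phi) - 4 * pi * a2 * sin(4 * pi * phi)

#' Simulate one walk-test session with full ground truth
#'
#' @param cfg a [gait_sim_config()].
#' @param subject_id label attached to the sensor set.
#' @return list of class `gait_simulation` with elements
#'   \describe{
#'     \item{set}{a [sensor_set()] with the three 9-DOF streams,}
#'     \item{truth}{ground truth: `ic_left`, `ic_right` (initial-contact
#'       times), `strides_left`, `strides_right`, `step_count`, `turn_times`,
#'       `distance_m`, `t_walk` (walk interval), true per-sample Euler angles
#'       per placement (`angles`), true quaternions (`quat`), and the exact
#'       zero-referenced 101-point sagittal profile per limb
#'       (`profile_left`, `profile_right`),}
#'     \item{config}{the configuration used.}
#'   }
#' @export
simulate_session <- function(cfg = gait_sim_config(), subject_id = "sim") {
  stopifnot(inherits(cfg, "gait_sim_config"))
  set.seed(cfg$seed)
  fs <- cfg$cadence_spm / 120            # strides per second
  S <- round(cfg$cadence_spm * cfg$duration_s / 60)  # target step count
  phi_start <- -0.3
  phi_end <- S / 2 + 0.1
  t_w0 <- cfg$lead_s
  walk_dur <- (phi_end - phi_start) / fs
  t_w1 <- t_w0 + walk_dur
  total <- t_w1 + cfg$tail_s
  dt <- 1 / cfg$rate_hz
  t <- seq(0, total, by = dt)
  n <- length(t)

  phi_raw <- phi_start + fs * (t - t_w0)
  walking <- phi_raw > phi_start & phi_raw < phi_end
  phi <- pmax(phi_start, pmin(phi_end, phi_raw))
  dphi <- ifelse(walking, fs, 0)

  # turns: every crossing of a course length; constant cadence throughout
  stride_len <- 2 * cfg$step_length_m
  L <- cfg$course$straight_length_m
  k_max <- floor(phi_end * stride_len / L)
  turn_phi <- (seq_len(k_max) * L) / stride_len
  turn_phi <- turn_phi[turn_phi < phi_end]
  turn_times <- t_w0 + (turn_phi - phi_start) / fs
  heading <- rep(0, n)
  for (tk in turn_times) {
    u <- (t - (tk - 1)) / 2
    heading <- heading + cfg$course$turn_angle_deg * smoothstep(u)
  }

  asym <- cfg$asymmetry
  a1 <- cfg$shank_sagittal_rom_deg / 2 * c(left = asym[[1L]], right = asym[[2L]])
  a2 <- 0.15 * a1

  two_pi <- 2 * pi
  osc <- function(amp, ph) amp * sin(two_pi * ph)

  euler <- list()   # per placement: yaw, pitch, roll (degrees)
  phL <- phi; phR <- phi - 0.5
  euler$left_shank <- list(
    yaw = heading + osc(cfg$shank_transverse_amp_deg, phL),
    pitch = stride_template(phL, a1[["left"]], a2[["left"]]),
    roll = osc(cfg$shank_frontal_amp_deg, phL)
  )
  euler$right_shank <- list(
    yaw = heading + osc(cfg$shank_transverse_amp_deg, phR),
    pitch = stride_template(phR, a1[["right"]], a2[["right"]]),
    roll = osc(cfg$shank_frontal_amp_deg, phR)
  )
  euler$sacrum <- list(
    yaw = heading + cfg$pelvic_yaw_amp_deg * cos(two_pi * phi),
    pitch = cfg$pelvic_tilt_deg + osc(cfg$pelvic_tilt_osc_deg, 2 * phi),
    roll = osc(cfg$pelvic_roll_amp_deg, phi)
  )

  d2r <- pi / 180
  m_world <- c(0.22, 0, -0.41)   # Gauss; typical mid-latitude field, z up
  streams <- list(); quats <- list(); angmats <- list()
  for (p in names(euler)) {
    e <- euler[[p]]
    yr <- e$yaw * d2r; pr <- e$pitch * d2r; rr <- e$roll * d2r
    # quaternions (vectorised composition of the three elemental rotations)
    cy <- cos(yr / 2); sy <- sin(yr / 2)
    cp <- cos(pr / 2); sp <- sin(pr / 2)
    cr <- cos(rr / 2); sr <- sin(rr / 2)
    qm <- cbind(cy * cp * cr + sy * sp * sr,
                cy * cp * sr - sy * sp * cr,
                cy * sp * cr + sy * cp * sr,
                sy * cp * cr - cy * sp * sr)
    # body->world matrix R = Rz(yaw) Ry(pitch) Rx(roll); sensors measure
    # world-frame references pulled back into the body frame via R^T
    cY <- cos(yr); sY <- sin(yr); cP <- cos(pr); sP <- sin(pr)
    cR <- cos(rr); sR <- sin(rr)
    # body->world rotation matrix entries
    r11 <- cY * cP; r12 <- cY * sP * sR - sY * cR; r13 <- cY * sP * cR + sY * sR
    r21 <- sY * cP; r22 <- sY * sP * sR + cY * cR; r23 <- sY * sP * cR - cY * sR
    r31 <- -sP;     r32 <- cP * sR;               r33 <- cP * cR
    bob <- ifelse(walking, cfg$acc_bob_g * sin(two_pi * 2 * phi), 0)
    gzw <- 1 + bob   # specific force along world z, g
    acc <- cbind(r31 * gzw, r32 * gzw, r33 * gzw)
    mag <- cbind(r11 * m_world[1L] + r21 * m_world[2L] + r31 * m_world[3L],
                 r12 * m_world[1L] + r22 * m_world[2L] + r32 * m_world[3L],
                 r13 * m_world[1L] + r23 * m_world[2L] + r33 * m_world[3L])
    # gyro = per-interval body-frame rotation increment / dt, exactly what a
    # strap-down sensor reports: integrating it reproduces the true
    # orientation to floating-point accuracy. It equals the instantaneous
    # body angular rate to O(dt^2). Vectorised dq_k = conj(q_k) * q_{k+1}.
    A <- qm[-n, , drop = FALSE]; B <- qm[-1L, , drop = FALSE]
    dqw <- A[, 1L] * B[, 1L] + A[, 2L] * B[, 2L] + A[, 3L] * B[, 3L] + A[, 4L] * B[, 4L]
    dqx <- A[, 1L] * B[, 2L] - A[, 2L] * B[, 1L] - A[, 3L] * B[, 4L] + A[, 4L] * B[, 3L]
    dqy <- A[, 1L] * B[, 3L] + A[, 2L] * B[, 4L] - A[, 3L] * B[, 1L] - A[, 4L] * B[, 2L]
    dqz <- A[, 1L] * B[, 4L] - A[, 2L] * B[, 3L] + A[, 3L] * B[, 2L] - A[, 4L] * B[, 1L]
    flip <- dqw < 0
    dqw[flip] <- -dqw[flip]; dqx[flip] <- -dqx[flip]
    dqy[flip] <- -dqy[flip]; dqz[flip] <- -dqz[flip]
    vn <- sqrt(dqx^2 + dqy^2 + dqz^2)
    scale <- ifelse(vn < 1e-12, 2 / dt, 2 * atan2(vn, dqw) / (vn * dt)) / d2r
    gyro <- cbind(dqx * scale, dqy * scale, dqz * scale)
    gyro <- rbind(gyro, gyro[nrow(gyro), ])   # final sample: hold last rate
    gyro <- sweep(gyro, 2L, cfg$gyro_bias_dps, "+")
    if (cfg$noise_sd[["acc_g"]] > 0)
      acc <- acc + matrix(stats::rnorm(3 * n, 0, cfg$noise_sd[["acc_g"]]), n)
    if (cfg$noise_sd[["gyro_dps"]] > 0)
      gyro <- gyro + matrix(stats::rnorm(3 * n, 0, cfg$noise_sd[["gyro_dps"]]), n)
    if (cfg$noise_sd[["mag_gauss"]] > 0)
      mag <- mag + matrix(stats::rnorm(3 * n, 0, cfg$noise_sd[["mag_gauss"]]), n)
    streams[[p]] <- sensor_stream(t, acc, gyro, mag, placement = p,
                                  rate_hz = cfg$rate_hz)
    quats[[p]] <- qm
    angmats[[p]] <- cbind(roll = e$roll, pitch = e$pitch, yaw = e$yaw)
  }

  ic_phi_left <- seq(0, floor(phi_end))
  ic_phi_right <- seq(0.5, phi_end, by = 1)
  ic_left <- t_w0 + (ic_phi_left - phi_start) / fs
  ic_right <- t_w0 + (ic_phi_right - phi_start) / fs

  # exact zero-referenced sagittal stride profiles (101 points): template
  # over one stride minus the standing (calibration) template value
  ref_profile <- function(limb) {
    a1v <- a1[[limb]]; a2v <- a2[[limb]]
    ph_stand <- phi_start - if (limb == "left") 0 else 0.5
    grid <- seq(0, 1, length.out = 101L)
    stride_template(grid, a1v, a2v) - stride_template(ph_stand, a1v, a2v)
  }

  truth <- list(
    ic_left = ic_left, ic_right = ic_right,
    strides_left = length(ic_left) - 1L,
    strides_right = length(ic_right) - 1L,
    step_count = S,
    turn_times = turn_times,
    distance_m = S * cfg$step_length_m,
    t_walk = c(t_w0, t_w1),
    angles = angmats, quat = quats, t = t,
    profile_left = ref_profile("left"),
    profile_right = ref_profile("right")
  )
  structure(list(
    set = sensor_set(streams$left_shank, streams$right_shank, streams$sacrum,
                     subject_id = subject_id),
    truth = truth, config = cfg
  ), class = "gait_simulation")
}

#' @export
print.gait_simulation <- function(x, ...) {
  cat(sprintf(
    "<gait_simulation> %d steps over %.0f s (%d turns, %.0f m), %d samples/sensor\n",
    x$truth$step_count, diff(x$truth$t_walk), length(x$truth$turn_times),
    x$truth$distance_m, length(x$truth$t)))
  invisible(x)
}
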