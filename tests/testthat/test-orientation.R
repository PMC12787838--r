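test_that("gyro bias estimation returns the static-window mean rate", {
  expect_equal(estimate_gyro_bias(make_static_stream(5)), c(0, 0, 0))
  s <- make_static_stream(5, gyro = c(1.0, -0.5, 0.2))
  expect_equal(unname(estimate_gyro_bias(s)), c(1.0, -0.5, 0.2))
  expect_error(estimate_gyro_bias(make_static_stream(1.5)), "shorter than 2 s")
  expect_error(estimate_gyro_bias(make_static_stream(5, gyro = c(80, 0, 0))),
               "not static")
})

test_that("injected simulator bias is recovered exactly from the standing lead", {
  bias <- c(2.1, -1.3, 0.4)
  sim <- simulate_session(gait_sim_config(duration_s = 20, gyro_bias_dps = bias,
                                          seed = 4))
  w <- slice_window(sim$set$streams$left_shank, 0, 5)
  expect_equal(unname(estimate_gyro_bias(w)), bias, tolerance = 1e-9)
})

test_that("pure strap-down integration matches closed-form rotation", {
  # zero rotation stays at the initial identity orientation
  s0 <- make_static_stream(2)
  ser0 <- strapdown_integrate(s0, fusion = fusion_config(accel_weight = 0,
                                                         mag_weight = 0))
  expect_equal(max(abs(ser0$roll)) + max(abs(ser0$pitch)) + max(abs(ser0$yaw)),
               0, tolerance = 1e-9)

  # constant 10 deg/s about the pitch axis for 2 s ends at 20 degrees
  s1 <- make_static_stream(2, gyro = c(0, 10, 0))
  ser1 <- strapdown_integrate(s1, fusion = fusion_config(accel_weight = 0,
                                                         mag_weight = 0))
  expect_equal(ser1$pitch[nrow(ser1)], 20, tolerance = 1e-6)

  # piecewise-constant rates vs the per-interval quaternion-product oracle
  set.seed(31)
  rate <- 60; dt <- 1 / rate
  t <- seq(0, 60 - dt, by = dt)
  seg <- pmin(12L, floor(t / 5) + 1L)
  rates <- matrix(stats::runif(36, -80, 80), 12L)
  gyro <- rates[seg, , drop = FALSE]
  n <- length(t)
  s2 <- sensor_stream(t, matrix(0, n, 3), gyro, matrix(0, n, 3),
                      "left_shank", rate)
  ser2 <- strapdown_integrate(s2, fusion = fusion_config(accel_weight = 0,
                                                         mag_weight = 0))
  qo <- oracle_quat_product(gyro, dt)
  qs <- as.matrix(ser2[, c("qw", "qx", "qy", "qz")])
  disc <- vapply(seq_len(n), function(k) quat_angle_deg(qs[k, ], qo[k, ]),
                 numeric(1L))
  expect_lt(max(disc), 0.01)
  # unit norm preserved throughout
  expect_lt(max(abs(sqrt(rowSums(qs^2)) - 1)), 1e-6)
})

test_that("complementary fusion pulls a misaligned estimate back to reference", {
  rate <- 60
  s <- make_static_stream(12, rate = rate, placement = "sacrum")
  for (q0 in list(quat_from_euler(0, 0, 5), quat_from_euler(5, 0, 0),
                  quat_from_euler(3, 3, 3))) {
    ser <- strapdown_integrate(
      s, fusion = fusion_config(mag_ref = c(0.22, 0, -0.41)), q0 = q0)
    qs <- as.matrix(ser[, c("qw", "qx", "qy", "qz")])
    err <- vapply(seq_len(nrow(qs)), function(k)
      quat_angle_deg(qs[k, ], c(1, 0, 0, 0)), numeric(1L))
    expect_gte(err[1L], 4.9)
    expect_lt(err[10 * rate], 0.1)
    coarse <- err[seq(1L, 10L * rate, by = 30L)]
    expect_true(all(diff(coarse) <= 1e-9))
  }
})

test_that("non-finite samples are rejected with their index", {
  s <- make_static_stream(2)
  s$gyro_y[17] <- NaN
  expect_error(strapdown_integrate(s), "index 17")
})

test_that("zero-phase low-pass keeps DC and the gait band, kills high frequencies", {
  rate <- 60
  t <- seq(0, 30, by = 1 / rate)
  n <- length(t)
  const <- make_static_stream(30, acc = c(0.1, -0.2, 0.9))
  out <- lowpass_filter(const, 6)
  expect_equal(out$acc_x, const$acc_x, tolerance = 1e-9)

  two_tone <- sin(2 * pi * 1 * t) + sin(2 * pi * 25 * t)
  s <- sensor_stream(t, cbind(two_tone, 0, 1), matrix(0, n, 3),
                     matrix(0, n, 3), "left_shank", rate)
  f <- lowpass_filter(s, 6)
  amp_at <- function(x, freq) {
    sp <- stats::fft(x)
    idx <- round(freq * 30) + 1L
    2 * Mod(sp[idx]) / length(x)
  }
  expect_lt(amp_at(f$acc_x, 25) / amp_at(s$acc_x, 25), 10^(-20 / 20))
  expect_equal(amp_at(f$acc_x, 1), amp_at(s$acc_x, 1), tolerance = 0.05)
  # idempotence within passband ripple on the 1 Hz tone
  ff <- lowpass_filter(f, 6)
  expect_equal(amp_at(ff$acc_x, 1), amp_at(f$acc_x, 1), tolerance = 0.02)
  expect_error(lowpass_filter(s, 30), "Nyquist")
})

test_that("zero-referencing zeroes the standing posture except pelvic tilt", {
  sim <- simulate_session(gait_sim_config(duration_s = 20, seed = 6,
                                          pelvic_tilt_deg = 21.5))
  fset <- sim$set
  calib <- calibrate(fset, 0, 5)
  # a series identical to the reference orientation reads 0 in every plane
  q_ref <- calib$reference_orientation$left_shank
  flat <- orientation_series(seq(0, 1, by = 1 / 60),
                             matrix(q_ref, 61, 4, byrow = TRUE), "left_shank")
  z <- zero_reference(flat, calib)
  expect_lt(max(abs(c(z$roll, z$pitch, z$yaw))), 1e-6)

  # sacrum: frontal/transverse zeroed, sagittal keeps the absolute tilt
  q_p <- calib$reference_orientation$sacrum
  flat_p <- orientation_series(seq(0, 1, by = 1 / 60),
                               matrix(q_p, 61, 4, byrow = TRUE), "sacrum")
  zp <- zero_reference(flat_p, calib)
  expect_lt(max(abs(c(zp$roll, zp$yaw))), 1e-6)
  expect_equal(mean(zp$pitch), 21.5, tolerance = 0.1)

  # idempotent: re-applying the same calibration changes nothing
  zz <- zero_reference(zp, calib)
  expect_identical(zz$pitch, zp$pitch)
  expect_identical(zz$yaw, zp$yaw)

  expect_error(zero_reference(flat, calib, placement = "elbow"),
               "calibration error")
})

test_that("relative angles recovered through the estimator match ground truth", {
  # pure rotational motion: recovery of the reference itself, not robustness
  # to stride-impact acceleration (that is covered by the end-to-end checks)
  sim <- simulate_session(gait_sim_config(duration_s = 30, seed = 8,
                                          acc_bob_g = 0))
  res <- suppressMessages(analyze_session(sim$set))
  tru <- sim$truth$angles$left_shank
  est <- res$angles$left_shank
  # simulator standing pose is the reference: truth zeroed the same way;
  # skip 1 s around the gait-onset velocity step, where the anti-noise
  # filter necessarily rings
  sel <- est$t > sim$truth$t_walk[1L] + 1 & est$t < sim$truth$t_walk[2L] - 1
  pitch_rel <- tru[, "pitch"] - tru[1L, "pitch"]
  roll_rel <- tru[, "roll"] - tru[1L, "roll"]
  expect_lt(max(abs((est$pitch - pitch_rel)[sel])), 0.1)
  expect_lt(max(abs((est$roll - roll_rel)[sel])), 0.1)
})
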