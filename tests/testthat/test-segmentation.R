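static_set <- function(duration = 30) {
  sensor_set(make_static_stream(duration, placement = "left_shank"),
             make_static_stream(duration, placement = "right_shank"),
             make_static_stream(duration, placement = "sacrum"))
}

test_that("activity classification labels static, dynamic and unidentified", {
  seg <- classify_activity(static_set())
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$label, "static")
  expect_equal(c(seg$t_start, seg$t_end), c(0, 30))

  # RMS exactly between the thresholds is unidentified
  mid <- sensor_set(
    make_static_stream(10, gyro = c(20, 0, 0), placement = "left_shank"),
    make_static_stream(10, gyro = c(20, 0, 0), placement = "right_shank"),
    make_static_stream(10, placement = "sacrum"))
  expect_equal(classify_activity(mid)$label, "unidentified")

  expect_error(classify_activity(static_set(5), window_s = 10), "config error")
  expect_error(classify_activity(static_set(), static_thresh_dps = 40),
               "static < dynamic")
})

test_that("segments tile a simulated walk with boundaries near ground truth", {
  sim <- shared_sim()
  seg <- classify_activity(sim$set)
  # exact tiling: no gaps, no overlaps
  expect_equal(seg$t_start[-1L], seg$t_end[-nrow(seg)])
  expect_equal(seg$t_start[1L], min(sim$set$streams$left_shank$t))
  labs <- rle(seg$label)$values
  expect_true(labs[1L] == "static" && labs[length(labs)] == "static")
  expect_true("dynamic" %in% labs)
  dyn <- seg[seg$label == "dynamic", ]
  expect_lt(abs(dyn$t_start[1L] - sim$truth$t_walk[1L]), 1.5)
  expect_lt(abs(dyn$t_end[nrow(dyn)] - sim$truth$t_walk[2L]), 1.5)
})

test_that("cycle detection recovers every simulated stride at its contact time", {
  sim <- shared_sim()
  for (limb in c("left", "right")) {
    pl <- paste0(limb, "_shank")
    cyc <- detect_cycles(truth_orientation(sim, pl), limb)
    truth_ic <- sim$truth[[paste0("ic_", limb)]]
    expect_equal(nrow(cyc), sim$truth[[paste0("strides_", limb)]])
    expect_lt(max(abs(cyc$t_ic - truth_ic[seq_len(nrow(cyc))])), 1 / 60)
    expect_true(all(diff(cyc$t_ic) > 0))
    expect_true(all(cyc$t_ic < cyc$t_end))
  }
})

test_that("cycle detection on a static recording yields an empty diagnostic result", {
  ser <- truth_orientation(shared_sim(), "left_shank")
  static_part <- ser[ser$t < 8, ]
  static_part <- orientation_series(
    static_part$t, as.matrix(static_part[, c("qw", "qx", "qy", "qz")]),
    "left_shank")
  cyc <- detect_cycles(static_part, "left")
  expect_equal(nrow(cyc), 0L)
  expect_true(nzchar(attr(cyc, "diagnostic")))
})

test_that("initiating limb follows pelvic yaw with a timing fallback", {
  res <- shared_analysis()
  sim <- shared_sim()
  p <- res$pairs[res$pairs$quality == "accepted", ]
  truth_init <- ifelse(p$left_t_ic <= p$right_t_ic, "left", "right")
  expect_gte(mean(p$initiating_limb == truth_init), 0.95)
  expect_gte(mean(p$initiating_confident), 0.90)

  # flat pelvic yaw: fallback on timing, ambiguity flagged
  t <- seq(0, 10, by = 1 / 60)
  flat <- orientation_series(t, matrix(c(1, 0, 0, 0), length(t), 4,
                                       byrow = TRUE), "sacrum")
  left <- list(t_ic = 4.0, t_end = 5.2)
  right <- list(t_ic = 4.6, t_end = 5.8)
  out <- determine_initiating_limb(flat, left, right)
  expect_equal(out$limb, "left")
  expect_false(out$confident)
  out2 <- determine_initiating_limb(flat, list(t_ic = 4.7, t_end = 5.9), right)
  expect_equal(out2$limb, "right")
})

test_that("pairing is symmetric, rejects bad cycles, and handles empty input", {
  left <- make_cycles_df(seq(0, 9), "left", duration = 1)
  right <- make_cycles_df(seq(0.5, 9.5), "right", duration = 1)
  p1 <- pair_and_filter(left, right)
  expect_equal(nrow(p1), 10L)
  expect_true(all(p1$quality == "accepted"))
  # symmetric in argument order
  p2 <- pair_and_filter(right, left)
  expect_equal(p2$left_t_ic, p1$left_t_ic)
  expect_equal(p2$right_t_ic, p1$right_t_ic)

  # a doubled-duration cycle is rejected with a duration reason
  left2 <- left
  left2$duration[5L] <- 2; left2$t_end[5L] <- left2$t_ic[5L] + 2
  p3 <- pair_and_filter(left2, right)
  bad <- p3[p3$quality == "rejected", ]
  expect_equal(nrow(bad), 1L)
  expect_match(bad$reject_reason, "duration")

  # low range of motion is rejected with a ROM reason
  left3 <- left
  left3$rom_deg[2L] <- 3
  p4 <- pair_and_filter(left3, right)
  expect_match(p4$reject_reason[p4$quality == "rejected"], "ROM")

  expect_equal(nrow(pair_and_filter(left, right[0, ])), 0L)
})

test_that("cycle normalization is exact on ramps and invariant to time warping", {
  t <- seq(0, 2, by = 1 / 600)
  ramp <- orientation_series(
    t, t(vapply(5 * t, function(p) quat_from_euler(0, p, 0), numeric(4L))),
    "left_shank")
  cyc <- list(t_ic = 0.3, t_end = 1.7)
  out <- normalize_cycle(ramp, cyc, "sagittal")
  expect_equal(length(out), 101L)
  expect_equal(out, seq(5 * 0.3, 5 * 1.7, length.out = 101), tolerance = 1e-9)

  cst <- orientation_series(
    t, matrix(quat_from_euler(0, 7, 0), length(t), 4, byrow = TRUE),
    "left_shank")
  expect_equal(normalize_cycle(cst, cyc, "sagittal"), rep(7, 101L),
               tolerance = 1e-9)
  expect_error(normalize_cycle(ramp, list(t_ic = 1.5, t_end = 2.5), "sagittal"),
               "bounds error")

  # same template walked at 0.9 s and 1.2 s gives the same normalized curve
  shape <- function(tt, dur)
    10 * cos(2 * pi * tt / dur) + 1.5 * cos(4 * pi * tt / dur)
  mk <- function(dur) {
    tt <- seq(0, dur, by = 1 / 60)
    orientation_series(
      tt, t(vapply(shape(tt, dur), function(p) quat_from_euler(0, p, 0),
                   numeric(4L))), "left_shank")
  }
  n1 <- normalize_cycle(mk(0.9), list(t_ic = 0, t_end = 0.9), "sagittal")
  n2 <- normalize_cycle(mk(1.2), list(t_ic = 0, t_end = 1.2), "sagittal")
  expect_equal(n1, n2, tolerance = 0.05)
})

test_that("profile statistics use pointwise mean and n-1 SD", {
  base <- sin(seq(0, 2 * pi, length.out = 101))
  p1 <- profile_stats(list(base, base, base))
  expect_equal(p1$mean_deg, base)
  expect_equal(p1$sd_deg, rep(0, 101))
  expect_equal(p1$n_cycles, 3L)

  p2 <- profile_stats(list(base, base + 2))
  expect_equal(p2$sd_deg, rep(sqrt(2), 101), tolerance = 1e-12)

  p3 <- profile_stats(list(base))
  expect_equal(p3$sd_deg, rep(0, 101))

  set.seed(94)
  noisy <- lapply(1:100, function(i) base + stats::rnorm(101, 0, 1))
  p4 <- profile_stats(noisy)
  expect_true(all(p4$sd_deg > 0.8 & p4$sd_deg < 1.2))

  expect_error(profile_stats(list()), "insufficient-data")
})
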