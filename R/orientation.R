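#' Orientation series
#'
#' Per-sample orientation of one sensor: unit quaternions (body-to-world) and
#' the derived Euler angles, intrinsic Z-Y'-X'' (yaw, pitch, roll) in degrees,
#' each in (-180, 180]. Anatomical plane mapping for a segment-aligned
#' sensor: sagittal = pitch, frontal = roll, transverse = yaw; negative roll
#' and negative yaw denote leftward rotation.
#'
#' @param t sample times, seconds.
#' @param qm n x 4 matrix of unit quaternions (w, x, y, z).
#' @param placement placement label.
#' @return object of class `orientation_series`: data frame with columns
#'   `t`, `qw`, `qx`, `qy`, `qz`, `roll`, `pitch`, `yaw`.
#' @export
orientation_series <- function(t, qm, placement) {
  qm <- matrix(qm, ncol = 4L)
  eul <- quat_to_euler_matrix(qm)
  structure(
    data.frame(t = t, qw = qm[, 1L], qx = qm[, 2L], qy = qm[, 3L],
               qz = qm[, 4L], roll = eul[, "roll"], pitch = eul[, "pitch"],
               yaw = eul[, "yaw"]),
    placement = placement, zeroed = FALSE,
    class = c("orientation_series", "data.frame")
  )
}

#' @export
print.orientation_series <- function(x, ...) {
  cat(sprintf("<orientation_series> %s, %d samples, %.1f s%s\n",
              attr(x, "placement"), nrow(x), diff(range(x$t)),
              if (isTRUE(attr(x, "zeroed"))) ", zero-referenced" else ""))
  invisible(x)
}

plane_to_angle <- c(sagittal = "pitch", frontal = "roll", transverse = "yaw")

#' Fusion parameters for the orientation estimator
#'
#' The estimator is a complementary filter: the gyroscope is integrated
#' sample-by-sample (the high-frequency path) and each update is nudged
#' toward the accelerometer's gravity direction and the magnetometer's
#' reference field (the low-frequency path). `accel_weight` and `mag_weight`
#' are the fraction of the observed orientation error corrected per update;
#' at 60 Hz the defaults give time constants of roughly 0.8 s (tilt) and
#' 1.7 s (heading), sized so that a 5-degree static misalignment decays
#' below 0.1 degrees within 10 s. Accelerometer corrections are gated out
#' when the
#' specific-force magnitude deviates from 1 g by more than `acc_gate`, so
#' stride impacts do not pollute the tilt estimate.
#'
#' @param accel_weight,mag_weight per-update correction fractions in `[0, 1]`.
#' @param lowpass_cutoff_hz cutoff of the zero-phase pre-filter, Hz. 6 Hz
#'   covers the human gait band (below ~5 Hz) with margin.
#' @param acc_gate acceptance band around 1 g for accelerometer corrections.
#' @param mag_ref optional world-frame magnetic reference (3-vector, Gauss);
#'   when `NULL` the first sample's field, rotated by the initial
#'   orientation, is used.
#' @return a `fusion_config` list.
#' @export
fusion_config <- function(accel_weight = 0.02, mag_weight = 0.01,
                          lowpass_cutoff_hz = 6, acc_gate = 0.1,
                          mag_ref = NULL) {
  if (accel_weight < 0 || accel_weight > 1 || mag_weight < 0 || mag_weight > 1)
    stop("fusion weights must lie in [0, 1]")
  if (lowpass_cutoff_hz <= 0) stop("lowpass cutoff must be positive")
  structure(list(accel_weight = accel_weight, mag_weight = mag_weight,
                 lowpass_cutoff_hz = lowpass_cutoff_hz, acc_gate = acc_gate,
                 mag_ref = mag_ref),
            class = "fusion_config")
}

#' Estimate the gyroscope bias from a static window
#'
#' The per-axis mean angular rate over a standing window estimates the
#' constant rate offset of the gyroscope, removed before integration.
#'
#' @param static_window a [sensor_stream()] covering at least 2 s of a
#'   static (standing/sitting) interval.
#' @param max_rms_dps guard: the window is rejected as dynamic when the RMS
#'   gyro magnitude exceeds this (deg/s).
#' @return 3-vector bias in deg/s.
#' @export
estimate_gyro_bias <- function(static_window, max_rms_dps = 10) {
  stopifnot(inherits(static_window, "sensor_stream"))
  if (diff(range(static_window$t)) < 2)
    stop("precondition error: static window shorter than 2 s")
  g <- as.matrix(static_window[, c("gyro_x", "gyro_y", "gyro_z")])
  rms <- sqrt(mean(rowSums(g^2)))
  if (rms > max_rms_dps)
    stop("precondition error: window is not static (RMS gyro ",
         round(rms, 1), " deg/s)")
  unname(colMeans(g))
}

#' Zero-phase low-pass filter of a sensor stream
#'
#' Forward-backward (zero group delay) 4th-order Butterworth low-pass applied
#' to every accelerometer, gyroscope and magnetometer channel. DC gain is
#' exactly 1, so static postures are untouched.
#'
#' @inheritParams validate_stream
#' @param cutoff_hz cutoff frequency, must be below the Nyquist rate.
#' @return filtered [sensor_stream()].
#' @export
lowpass_filter <- function(stream, cutoff_hz = 6) {
  stopifnot(inherits(stream, "sensor_stream"))
  rate <- attr(stream, "rate_hz")
  if (cutoff_hz >= rate / 2)
    stop("config error: cutoff ", cutoff_hz, " Hz >= Nyquist ", rate / 2, " Hz")
  bf <- signal::butter(4, cutoff_hz / (rate / 2), type = "low")
  out <- stream
  n <- nrow(stream)
  # odd-reflection padding suppresses the start/end transients of the
  # forward-backward pass (which would otherwise leak into the standing
  # calibration window); a constant signal stays exactly constant
  p <- min(n - 1L, as.integer(ceiling(3 * rate / cutoff_hz)))
  for (ch in setdiff(names(stream), "t")) {
    x <- stream[[ch]]
    mu <- mean(x)
    xc <- x - mu   # filter the fluctuation only: DC passes untouched
    if (p > 0L) {
      xp <- c(2 * xc[1L] - xc[(p + 1L):2L], xc,
              2 * xc[n] - xc[(n - 1L):(n - p)])
      y <- as.numeric(signal::filtfilt(bf, xp))[(p + 1L):(p + n)]
    } else y <- as.numeric(signal::filtfilt(bf, xc))
    out[[ch]] <- y + mu
  }
  structure(out, placement = attr(stream, "placement"),
            rate_hz = rate, class = c("sensor_stream", "data.frame"))
}

rotmat_to_quat <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] >= R[2, 2] && R[1, 1] >= R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s, (R[1, 2] + R[2, 1]) / s,
           (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] >= R[3, 3]) {
    s <- sqrt(1 - R[1, 1] + R[2, 2] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s, 0.25 * s,
           (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 - R[1, 1] - R[2, 2] + R[3, 3]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, 0.25 * s)
  }
  quat_normalize(q)
}

#' Initial orientation from accelerometer and magnetometer
#'
#' Mean specific force over a static window fixes the tilt (gravity is the
#' world +z reference); the mean magnetic field fixes the heading, taking
#' the horizontal field component as the world +x axis. This is the standard
#' two-vector (TRIAD) construction.
#'
#' @param window static [sensor_stream()].
#' @return unit quaternion (body to world).
#' @export
init_orientation <- function(window) {
  stopifnot(inherits(window, "sensor_stream"))
  g_b <- colMeans(as.matrix(window[, c("acc_x", "acc_y", "acc_z")]))
  g_b <- g_b / sqrt(sum(g_b^2))
  m_b <- colMeans(as.matrix(window[, c("mag_x", "mag_y", "mag_z")]))
  m_h <- m_b - sum(m_b * g_b) * g_b
  nm <- sqrt(sum(m_h^2))
  if (nm < 1e-9) {
    # magnetic field parallel to gravity: heading unobservable, pick any
    m_h <- if (abs(g_b[1L]) < 0.9) c(1, 0, 0) - g_b[1L] * g_b else
      c(0, 1, 0) - g_b[2L] * g_b
    nm <- sqrt(sum(m_h^2))
  }
  x_b <- m_h / nm
  y_b <- c(g_b[2L] * x_b[3L] - g_b[3L] * x_b[2L],
           g_b[3L] * x_b[1L] - g_b[1L] * x_b[3L],
           g_b[1L] * x_b[2L] - g_b[2L] * x_b[1L])
  # rows of R (body->world) are the world axes expressed in body coordinates
  R <- rbind(x_b, y_b, g_b)
  rotmat_to_quat(R)
}

#' Strap-down orientation integration with complementary correction
#'
#' Propagates a unit quaternion by the exact axis-angle increment of the
#' bias-corrected angular rate over each sampling interval (the rate at
#' sample k applies over `[t_k, t_{k+1})`, which is exact for
#' piecewise-constant rotation). With both fusion weights zero this is pure
#' gyroscopic dead reckoning; with nonzero weights each step is additionally
#' rotated a small fraction of the way toward agreement with the measured
#' gravity direction (tilt) and magnetic reference (heading), which bounds
#' the long-term drift.
#'
#' @inheritParams validate_stream
#' @param bias gyroscope bias (deg/s) to subtract, e.g. from
#'   [estimate_gyro_bias()].
#' @param fusion a [fusion_config()].
#' @param q0 initial orientation quaternion; identity by default (use
#'   [init_orientation()] on the standing window for an absolute start).
#' @return an [orientation_series()] of the same length as the stream.
#' @export
strapdown_integrate <- function(stream, bias = c(0, 0, 0),
                                fusion = fusion_config(), q0 = c(1, 0, 0, 0)) {
  stopifnot(inherits(stream, "sensor_stream"))
  M <- as.matrix(stream)
  if (any(!is.finite(M)))
    stop("numeric error: non-finite sample at index ",
         which(!apply(is.finite(M), 1L, all))[1L])
  n <- nrow(stream)
  t <- stream$t
  gx <- (stream$gyro_x - bias[1L]) * pi / 180
  gy <- (stream$gyro_y - bias[2L]) * pi / 180
  gz <- (stream$gyro_z - bias[3L]) * pi / 180
  ax <- stream$acc_x; ay <- stream$acc_y; az <- stream$acc_z
  wa <- fusion$accel_weight; wm <- fusion$mag_weight
  gate <- fusion$acc_gate
  q <- quat_normalize(q0)
  m_ref <- fusion$mag_ref
  if (is.null(m_ref) && wm > 0)
    m_ref <- quat_rotate(q, c(stream$mag_x[1L], stream$mag_y[1L],
                              stream$mag_z[1L]))
  qm <- matrix(0, n, 4L)
  qm[1L, ] <- q
  for (k in seq_len(n - 1L)) {
    dt <- t[k + 1L] - t[k]
    # gyro propagation: exact for a constant rate over the interval
    rv <- c(gx[k], gy[k], gz[k]) * dt
    ang <- sqrt(sum(rv * rv))
    if (ang > 0) {
      h <- ang / 2
      dq <- c(cos(h), (sin(h) / ang) * rv)
      q <- quat_multiply(q, dq)
    }
    j <- k + 1L
    if (wa > 0) {
      a <- c(ax[j], ay[j], az[j])
      na <- sqrt(sum(a * a))
      if (na > 0 && abs(na - 1) < gate) {
        v_meas <- a / na
        v_pred <- quat_rotate_inverse(q, c(0, 0, 1))
        e <- c(v_meas[2L] * v_pred[3L] - v_meas[3L] * v_pred[2L],
               v_meas[3L] * v_pred[1L] - v_meas[1L] * v_pred[3L],
               v_meas[1L] * v_pred[2L] - v_meas[2L] * v_pred[1L])
        se <- sqrt(sum(e * e))
        if (se > 1e-12) {
          theta <- asin(min(1, se))
          q <- quat_multiply(q, quat_from_axis_angle(e, wa * theta))
        }
      }
    }
    if (wm > 0) {
      m_w <- quat_rotate(q, c(stream$mag_x[j], stream$mag_y[j],
                              stream$mag_z[j]))
      # heading-only correction: signed horizontal angle, estimate -> reference
      cr <- m_w[1L] * m_ref[2L] - m_w[2L] * m_ref[1L]
      dt2 <- m_w[1L] * m_ref[1L] + m_w[2L] * m_ref[2L]
      if (abs(cr) + abs(dt2) > 1e-12) {
        psi <- atan2(cr, dt2)
        q <- quat_multiply(quat_from_axis_angle(c(0, 0, 1), wm * psi), q)
      }
    }
    q <- quat_normalize(q)
    qm[j, ] <- q
  }
  orientation_series(t, qm, attr(stream, "placement"))
}

#' Calibration state from the standing window
#'
#' A 5-s standing calibration at the start of the walk fixes, per placement,
#' the gyroscope bias and the reference orientation used to zero the angle
#' output (so that the habitual standing posture reads 0 degrees). The
#' sacrum's sagittal plane is exempt: pelvic tilt is reported as an absolute
#' angle, not relative to standing.
#'
#' @param set a [sensor_set()].
#' @param t0,t1 calibration window bounds, seconds (default the first 5 s).
#' @param zero_exempt list of `c(placement, plane)` pairs excluded from
#'   zero-referencing.
#' @return object of class `calibration_state`: per-placement `gyro_bias`
#'   and `reference_orientation`, plus `zero_exempt`.
#' @export
calibrate <- function(set, t0 = 0, t1 = 5,
                      zero_exempt = list(c("sacrum", "sagittal"))) {
  stopifnot(inherits(set, "sensor_set"))
  bias <- list(); ref <- list()
  for (p in names(set$streams)) {
    w <- slice_window(set$streams[[p]], t0, t1)
    bias[[p]] <- estimate_gyro_bias(w)
    ref[[p]] <- init_orientation(w)
  }
  structure(list(gyro_bias = bias, reference_orientation = ref,
                 zero_exempt = zero_exempt, window = c(t0, t1)),
            class = "calibration_state")
}

wrap180 <- function(x) ((x + 180) %% 360) - 180

# undo the (-180, 180] wrap of an angle series: cumulative heading in degrees
unwrap_deg <- function(y) {
  if (length(y) < 2L) return(y)
  d <- diff(y)
  d <- d - 360 * round(d / 360)
  cumsum(c(y[1L], d))
}

#' Express orientation angles relative to the standing reference
#'
#' Subtracts, per plane, the calibration reference angle from the series'
#' Euler angles, so the standing posture reads 0 degrees in every plane
#' except the exempt (placement, plane) pairs, which keep their absolute
#' angle (by default pelvic tilt: the sacrum's sagittal plane). Referencing
#' is per plane (component-wise on the Z-Y'-X'' angles) rather than via the
#' relative quaternion: with yaw as the outermost rotation this makes the
#' sagittal and frontal angles invariant to walking direction, so the
#' 180-degree course turns do not flip their sign. Frontal and transverse
#' differences are wrapped to (-180, 180]. The operation records itself on
#' the object and is idempotent: re-applying the same calibration is a
#' no-op.
#'
#' @param series an [orientation_series()].
#' @param calib a `calibration_state` from [calibrate()].
#' @param placement placement label (defaults to the series' own).
#' @return zero-referenced [orientation_series()].
#' @export
zero_reference <- function(series, calib, placement = attr(series, "placement")) {
  stopifnot(inherits(series, "orientation_series"))
  if (!inherits(calib, "calibration_state"))
    stop("calibration error: calib is not a calibration_state")
  if (isTRUE(attr(series, "zeroed"))) return(series)
  q_ref <- calib$reference_orientation[[placement]]
  if (is.null(q_ref))
    stop("calibration error: no reference orientation for ", placement)
  ref <- quat_to_euler(q_ref)
  out <- series
  out$roll <- wrap180(series$roll - ref[["roll"]])
  out$pitch <- series$pitch - ref[["pitch"]]
  out$yaw <- wrap180(series$yaw - ref[["yaw"]])
  for (ex in calib$zero_exempt) {
    if (identical(ex[1L], placement)) {
      ang <- plane_to_angle[[ex[2L]]]
      out[[ang]] <- series[[ang]]
    }
  }
  attr(out, "zeroed") <- TRUE
  out
}
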