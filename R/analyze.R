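#' Default pipeline configuration
#'
#' Nested list of every tunable parameter of the pipeline with its default,
#' so a bare run is fully reproducible. Sections: `orientation` (fusion
#' weights, pre-filter cutoff), `segmentation` (activity windows and
#' thresholds, cycle-detection and quality parameters), `metrics` (course
#' geometry, test duration, straight-segment rule) and `simulate` (the
#' simulator defaults).
#'
#' @return named nested list.
#' @export
default_config <- function() {
  list(
    orientation = list(accel_weight = 0.02, mag_weight = 0.01,
                       lowpass_cutoff_hz = 6, acc_gate = 0.1),
    segmentation = list(window_s = 1, static_thresh_dps = 10,
                        dynamic_thresh_dps = 30, duration_tol = 0.30,
                        min_rom_deg = 5, peak_frac = 0.3,
                        min_interval_s = 0.35),
    metrics = list(straight_length_m = 32, turn_angle_deg = 180,
                   duration_s = 360, min_straight_s = 5,
                   turn_halfwidth_s = 2),
    simulate = list(cadence_spm = 595 / 6, step_length_m = 0.6,
                    duration_s = 360, shank_sagittal_rom_deg = 20,
                    pelvic_tilt_deg = 21.5, noise_acc_g = 0,
                    noise_gyro_dps = 0, noise_mag_gauss = 0, seed = 1)
  )
}

#' Load a pipeline configuration file
#'
#' YAML file with any subset of the sections of [default_config()];
#' missing keys take their defaults, unknown keys are an error.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @return nested configuration list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read configuration files")
  user <- yaml::read_yaml(path)
  for (sec in names(user)) {
    if (!sec %in% names(cfg)) stop("unknown config section: ", sec)
    for (key in names(user[[sec]])) {
      if (!key %in% names(cfg[[sec]]))
        stop("unknown config key: ", sec, ".", key)
      cfg[[sec]][[key]] <- user[[sec]][[key]]
    }
  }
  cfg
}

#' Run the full gait-analysis pipeline on one session
#'
#' From raw sensor streams to gait metrics: zero-phase low-pass filtering,
#' activity classification, standing calibration (gyro bias + reference
#' orientation; 5 s by default), strap-down orientation estimation with
#' complementary drift correction, zero-referencing (pelvic tilt exempt),
#' per-limb gait-cycle detection restricted to dynamic segments, cycle
#' pairing with quality rejection, turn detection, walk metrics, per-minute
#' snapshots (minutes 1, 3, 6) and 0-100% normalized angle profiles.
#'
#' @param set a [sensor_set()].
#' @param config a configuration list from [default_config()] /
#'   [load_config()].
#' @param calib_window calibration window `c(t0, t1)` in seconds; the
#'   recording must be static there.
#' @return object of class `gait_analysis`; see [print.gait_analysis()].
#' @export
analyze_session <- function(set, config = default_config(),
                            calib_window = c(0, 5)) {
  stopifnot(inherits(set, "sensor_set"))
  oc <- config$orientation; sc <- config$segmentation; mc <- config$metrics
  filtered <- lapply(set$streams, lowpass_filter, cutoff_hz = oc$lowpass_cutoff_hz)
  fset <- sensor_set(filtered$left_shank, filtered$right_shank,
                     filtered$sacrum, subject_id = set$subject_id)
  segments <- classify_activity(fset, window_s = sc$window_s,
                                static_thresh_dps = sc$static_thresh_dps,
                                dynamic_thresh_dps = sc$dynamic_thresh_dps)
  calib <- calibrate(fset, calib_window[1L], calib_window[2L])
  fus <- fusion_config(accel_weight = oc$accel_weight,
                       mag_weight = oc$mag_weight,
                       lowpass_cutoff_hz = oc$lowpass_cutoff_hz,
                       acc_gate = oc$acc_gate)
  angles <- list()
  for (p in names(fset$streams)) {
    w <- slice_window(fset$streams[[p]], calib_window[1L], calib_window[2L])
    q0 <- init_orientation(w)
    ser <- strapdown_integrate(fset$streams[[p]], bias = calib$gyro_bias[[p]],
                               fusion = fus, q0 = q0)
    angles[[p]] <- zero_reference(ser, calib, p)
  }
  cyc_l <- detect_cycles(angles$left_shank, "left", attr(set$streams$left_shank, "rate_hz"),
                         segments = segments, peak_frac = sc$peak_frac,
                         min_interval_s = sc$min_interval_s)
  cyc_r <- detect_cycles(angles$right_shank, "right", attr(set$streams$right_shank, "rate_hz"),
                         segments = segments, peak_frac = sc$peak_frac,
                         min_interval_s = sc$min_interval_s)
  pairs <- pair_and_filter(cyc_l, cyc_r,
                           quality = list(duration_tol = sc$duration_tol,
                                          min_rom_deg = sc$min_rom_deg),
                           pelvic_yaw = angles$sacrum)
  course <- course_model(mc$straight_length_m, mc$turn_angle_deg)
  turns <- detect_turns(angles$sacrum, course)
  metrics <- walk_metrics(pairs, turns, course, duration_s = mc$duration_s)
  snaps <- list()
  for (m in c(1, 3, 6)) {
    s <- minute_snapshot(angles, segments, turns, m,
                         min_len_s = mc$min_straight_s,
                         turn_halfwidth_s = mc$turn_halfwidth_s)
    if (!is.null(s)) snaps[[length(snaps) + 1L]] <- s
  }
  snapshots <- if (length(snaps)) do.call(rbind, snaps) else NULL
  # normalized profiles over the cycles of accepted pairs
  acc_pairs <- pairs[pairs$quality == "accepted", , drop = FALSE]
  profiles <- list()
  cyc_of <- list(left_shank = cyc_l, right_shank = cyc_r, sacrum = cyc_l)
  for (p in names(angles)) {
    keep_tic <- if (p == "right_shank") acc_pairs$right_t_ic else acc_pairs$left_t_ic
    cyc <- cyc_of[[p]]
    cyc <- cyc[cyc$t_ic %in% keep_tic, , drop = FALSE]
    if (nrow(cyc) == 0L) next
    for (pl in names(plane_to_angle)) {
      curves <- lapply(seq_len(nrow(cyc)), function(i)
        normalize_cycle(angles[[p]], cyc[i, ], pl))
      profiles[[paste(p, pl, sep = ".")]] <-
        profile_stats(curves, plane = pl, placement = p)
    }
  }
  structure(list(
    subject_id = set$subject_id, segments = segments, calibration = calib,
    angles = angles, cycles_left = cyc_l, cycles_right = cyc_r,
    pairs = pairs, turns = turns, metrics = metrics, snapshots = snapshots,
    profiles = profiles, config = config,
    counts = list(
      samples = nrow(set$streams$left_shank),
      segments = nrow(segments),
      cycles_detected = nrow(cyc_l) + nrow(cyc_r),
      pairs_accepted = sum(pairs$quality == "accepted"),
      pairs_rejected = sum(pairs$quality == "rejected"))
  ), class = "gait_analysis")
}

#' @export
print.gait_analysis <- function(x, ...) {
  cat(sprintf("Gait analysis of subject %s\n", x$subject_id))
  cat(sprintf("  %d samples/sensor, %d activity segments\n",
              x$counts$samples, x$counts$segments))
  cat(sprintf("  cycles: %d left, %d right; pairs: %d accepted, %d rejected\n",
              nrow(x$cycles_left), nrow(x$cycles_right),
              x$counts$pairs_accepted, x$counts$pairs_rejected))
  m <- x$metrics
  cat(sprintf("  walk: %.1f m, %d steps, %.3f m/step, %.2f km/h, %d turns\n",
              m$distance_m, m$step_count, m$avg_step_length_m,
              m$mean_speed_kmh, m$n_turns))
  invisible(x)
}

#' @export
summary.gait_analysis <- function(object, ...) {
  print(object)
  if (!is.null(object$snapshots)) {
    cat("  per-minute snapshots (mean deg):\n")
    s <- object$snapshots
    for (m in unique(s$minute)) {
      sag <- s[s$minute == m & s$plane == "sagittal", ]
      cat(sprintf("    minute %d: sagittal left %.1f / right %.1f / pelvis %.1f\n",
                  m, sag$mean_deg[sag$placement == "left_shank"],
                  sag$mean_deg[sag$placement == "right_shank"],
                  sag$mean_deg[sag$placement == "sacrum"]))
    }
  }
  invisible(object)
}

#' Plot normalized gait profiles of an analyzed session
#'
#' Mean +/- SD sagittal (by default) angle over the 0-100% gait cycle for
#' both shanks.
#'
#' @param x a `gait_analysis` object.
#' @param plane plane to plot.
#' @param ... passed to [graphics::plot()].
#' @export
plot.gait_analysis <- function(x, plane = "sagittal", ...) {
  keys <- paste(c("left_shank", "right_shank"), plane, sep = ".")
  keys <- keys[keys %in% names(x$profiles)]
  if (!length(keys)) stop("no profiles available for plane ", plane)
  prof <- x$profiles[keys]
  rng <- range(unlist(lapply(prof, function(p)
    c(p$mean_deg - p$sd_deg, p$mean_deg + p$sd_deg))))
  graphics::plot(NA, xlim = c(0, 100), ylim = rng, xlab = "% gait cycle",
                 ylab = sprintf("%s angle (deg)", plane),
                 main = sprintf("Subject %s", x$subject_id), ...)
  cols <- c(left_shank = "firebrick", right_shank = "navy")
  for (k in keys) {
    p <- prof[[k]]
    col <- cols[[p$placement]]
    graphics::polygon(c(p$grid, rev(p$grid)),
                      c(p$mean_deg - p$sd_deg, rev(p$mean_deg + p$sd_deg)),
                      col = grDevices::adjustcolor(col, 0.2), border = NA)
    graphics::lines(p$grid, p$mean_deg, col = col, lwd = 2)
  }
  graphics::legend("topright", legend = sub("_shank", "", names(cols)),
                   col = cols, lwd = 2, bty = "n")
  invisible(x)
}
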