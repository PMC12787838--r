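#' Classify a recording into static / dynamic / unidentified activity
#'
#' The recording is cut into fixed windows; per window the RMS magnitude of
#' the shank gyroscopes (both limbs pooled) decides the label: below
#' `static_thresh_dps` the window is static (standing/sitting), above
#' `dynamic_thresh_dps` dynamic (walking/running), and in between
#' unidentified -- such intervals are excluded from locomotion analysis.
#' Adjacent windows with the same label are merged, so the returned segments
#' tile the recording exactly.
#'
#' @param set a [sensor_set()].
#' @param window_s window length, seconds.
#' @param static_thresh_dps,dynamic_thresh_dps RMS gyro thresholds, deg/s,
#'   with `static < dynamic`.
#' @return data frame of class `activity_segments` with columns `t_start`,
#'   `t_end`, `label`.
#' @export
classify_activity <- function(set, window_s = 1, static_thresh_dps = 10,
                              dynamic_thresh_dps = 30) {
  stopifnot(inherits(set, "sensor_set"))
  if (!(static_thresh_dps > 0 && static_thresh_dps < dynamic_thresh_dps))
    stop("thresholds must satisfy 0 < static < dynamic")
  ls <- set$streams$left_shank
  rs <- set$streams$right_shank
  t_lo <- max(min(ls$t), min(rs$t))
  t_hi <- min(max(ls$t), max(rs$t))
  if (window_s > t_hi - t_lo)
    stop("config error: window longer than the recording")
  edges <- seq(t_lo, t_hi, by = window_s)
  if (edges[length(edges)] < t_hi) edges <- c(edges, t_hi)
  g2 <- function(s) rowSums(as.matrix(s[, c("gyro_x", "gyro_y", "gyro_z")])^2)
  sq_l <- g2(ls); sq_r <- g2(rs)
  labs <- character(length(edges) - 1L)
  for (i in seq_along(labs)) {
    lo <- edges[i]; hi <- edges[i + 1L]
    last <- i == length(labs)
    in_l <- ls$t >= lo & (if (last) ls$t <= hi else ls$t < hi)
    in_r <- rs$t >= lo & (if (last) rs$t <= hi else rs$t < hi)
    vals <- c(sq_l[in_l], sq_r[in_r])
    rms <- if (length(vals)) sqrt(mean(vals)) else 0
    labs[i] <- if (rms < static_thresh_dps) "static"
      else if (rms > dynamic_thresh_dps) "dynamic" else "unidentified"
  }
  # merge adjacent equal labels
  keep <- c(TRUE, labs[-1L] != labs[-length(labs)])
  starts <- edges[-length(edges)][keep]
  ends <- c(starts[-1L], edges[length(edges)])
  structure(data.frame(t_start = starts, t_end = ends, label = labs[keep],
                       stringsAsFactors = FALSE),
            class = c("activity_segments", "data.frame"))
}

#' Detect gait cycles from shank orientation
#'
#' One gait cycle (stride) runs from one initial contact of a foot to the
#' next initial contact of the same foot. Initial contact is located at the
#' negative-going zero crossing of the shank's sagittal angular velocity
#' that follows the mid-swing velocity peak -- a standard single-shank-IMU
#' event heuristic. Candidate crossings must be preceded (since the previous
#' event) by a positive velocity peak of at least `peak_frac` of the robust
#' maximum, and events closer than `min_interval_s` are pruned, keeping the
#' one with the stronger preceding swing.
#'
#' @param shank_angles an [orientation_series()] for one shank.
#' @param limb `"left"` or `"right"`.
#' @param rate_hz sampling rate, Hz.
#' @param segments optional `activity_segments`; detection is restricted to
#'   dynamic segments (padded by `pad_s` so events at a segment edge are not
#'   lost to window quantization).
#' @param peak_frac fraction of the 95th-percentile positive velocity that a
#'   preceding swing peak must reach.
#' @param min_interval_s minimum separation between initial contacts.
#' @param pad_s padding added around dynamic segments, seconds.
#' @return data frame of class `gait_cycles` with columns `limb`, `t_ic`,
#'   `t_end`, `duration`, `rom_deg`, `quality`, `reject_reason`. Fewer than
#'   two detectable strides yields an empty table with a `diagnostic`
#'   attribute rather than an error.
#' @export
detect_cycles <- function(shank_angles, limb, rate_hz = 60, segments = NULL,
                          peak_frac = 0.3, min_interval_s = 0.35, pad_s = 1) {
  stopifnot(inherits(shank_angles, "orientation_series"))
  limb <- match.arg(limb, c("left", "right"))
  t <- shank_angles$t
  th <- shank_angles$pitch
  n <- length(t)
  empty <- function(msg) {
    out <- data.frame(limb = character(), t_ic = numeric(), t_end = numeric(),
                      duration = numeric(), rom_deg = numeric(),
                      quality = character(), reject_reason = character(),
                      stringsAsFactors = FALSE)
    structure(out, diagnostic = msg, class = c("gait_cycles", "data.frame"))
  }
  if (n < 3L) return(empty("series too short"))
  # sagittal angular velocity, central differences
  v <- c((th[2L] - th[1L]) / (t[2L] - t[1L]),
         (th[3:n] - th[1:(n - 2L)]) / (t[3:n] - t[1:(n - 2L)]),
         (th[n] - th[n - 1L]) / (t[n] - t[n - 1L]))
  in_dyn <- rep(TRUE, n)
  if (!is.null(segments)) {
    dyn <- segments[segments$label == "dynamic", , drop = FALSE]
    if (nrow(dyn) == 0L) return(empty("no dynamic segments"))
    in_dyn <- rep(FALSE, n)
    for (i in seq_len(nrow(dyn)))
      in_dyn <- in_dyn | (t >= dyn$t_start[i] - pad_s & t < dyn$t_end[i] + pad_s)
  }
  vpos <- v[in_dyn & v > 0]
  if (length(vpos) < 2L) return(empty("no positive-velocity swing phase"))
  peak_thresh <- peak_frac * stats::quantile(vpos, 0.95, names = FALSE)
  # negative-going zero crossings of v within the dynamic support
  idx <- which(v[-n] >= 0 & v[-1L] < 0 & in_dyn[-n] & in_dyn[-1L])
  if (length(idx) < 2L) return(empty("fewer than 2 candidate events"))
  t_ev <- numeric(0); strength <- numeric(0)
  prev_i <- 1L
  for (i in idx) {
    pk <- max(v[prev_i:i])
    if (pk >= peak_thresh) {
      # sub-sample crossing time by linear interpolation
      frac <- if (v[i] == v[i + 1L]) 0 else v[i] / (v[i] - v[i + 1L])
      t_ev <- c(t_ev, t[i] + frac * (t[i + 1L] - t[i]))
      strength <- c(strength, pk)
    }
    prev_i <- i + 1L
  }
  # prune events closer than the minimum inter-contact interval
  if (length(t_ev) > 1L) {
    keep <- rep(TRUE, length(t_ev))
    i <- 2L
    while (i <= length(t_ev)) {
      prev <- max(which(keep[seq_len(i - 1L)]))
      if (t_ev[i] - t_ev[prev] < min_interval_s) {
        if (strength[i] > strength[prev]) keep[prev] <- FALSE else keep[i] <- FALSE
      }
      i <- i + 1L
    }
    t_ev <- t_ev[keep]
  }
  if (length(t_ev) < 2L) return(empty("fewer than 2 detectable strides"))
  t_ic <- t_ev[-length(t_ev)]
  t_end <- t_ev[-1L]
  rom <- vapply(seq_along(t_ic), function(i) {
    sel <- t >= t_ic[i] & t <= t_end[i]
    if (!any(sel)) return(0) else diff(range(th[sel]))
  }, numeric(1L))
  structure(
    data.frame(limb = limb, t_ic = t_ic, t_end = t_end,
               duration = t_end - t_ic, rom_deg = rom,
               quality = "accepted", reject_reason = NA_character_,
               stringsAsFactors = FALSE),
    class = c("gait_cycles", "data.frame")
  )
}

#' Determine the limb that initiates a cycle pair
#'
#' Pelvic rotation about the vertical axis alternates with the stepping
#' side: at a left initial contact the (locally detrended) pelvic yaw sits
#' at its positive excursion, at a right contact at its negative excursion
#' (negative yaw = leftward rotation). The limb with the earlier initial
#' contact is the candidate initiator; the yaw signature at the two contacts
#' must be consistent with the limb labels, otherwise -- or when the yaw
#' excursion is flat -- the timing-based candidate is returned with the
#' ambiguity flag set.
#'
#' @param pelvic_yaw [orientation_series()] of the sacrum sensor.
#' @param left,right single-row entries of a `gait_cycles` table (or lists
#'   with `t_ic`, `t_end`).
#' @param min_excursion_deg yaw excursion below which the signature is
#'   considered ambiguous.
#' @return list with `limb` (`"left"` or `"right"`), `confident` (logical).
#' @export
determine_initiating_limb <- function(pelvic_yaw, left, right,
                                      min_excursion_deg = 0.5) {
  t0 <- min(left$t_ic, right$t_ic)
  t1 <- max(left$t_end, right$t_end)
  span <- t1 - t0
  sel <- pelvic_yaw$t >= t0 - 0.5 * span & pelvic_yaw$t <= t1 + 0.5 * span
  candidate <- if (left$t_ic <= right$t_ic) "left" else "right"
  tt <- pelvic_yaw$t[sel]
  yy <- unwrap_deg(pelvic_yaw$yaw[sel])
  if (length(tt) < 5L)
    return(list(limb = candidate, confident = FALSE))
  # remove heading (constant between turns, ramp during): local linear detrend
  fit <- stats::lm.fit(cbind(1, tt - t0), yy)
  yd <- fit$residuals
  y_at <- function(tq) stats::approx(tt, yd, xout = tq, rule = 2L)$y
  score <- y_at(left$t_ic) - y_at(right$t_ic)  # expected positive
  if (abs(score) < min_excursion_deg)
    return(list(limb = candidate, confident = FALSE))
  list(limb = candidate, confident = score > 0)
}

#' Pair left and right gait cycles and apply quality filtering
#'
#' Accepted cycles from both limbs are merged in time order; a pair is
#' formed from each maximal run of two consecutive opposite-limb cycles
#' (sequential alternation), which is symmetric in the order of the two
#' arguments and well defined when one limb misses a stride. A pair is
#' rejected when either cycle's duration deviates from the session median by
#' more than `duration_tol` (fraction) or its sagittal range of motion is
#' below `min_rom_deg`.
#'
#' @param left,right `gait_cycles` tables from [detect_cycles()].
#' @param quality list with `duration_tol` (default 0.30) and `min_rom_deg`
#'   (default 5).
#' @param pelvic_yaw optional sacrum [orientation_series()] used to set each
#'   pair's initiating limb; with `NULL` the earlier contact initiates.
#' @return data frame of class `cycle_pairs` with one row per pair:
#'   `t_start`, `t_end`, `left_t_ic`, `right_t_ic`, `initiating_limb`,
#'   `initiating_confident`, `quality`, `reject_reason`.
#' @export
pair_and_filter <- function(left, right,
                            quality = list(duration_tol = 0.30, min_rom_deg = 5),
                            pelvic_yaw = NULL) {
  dur_tol <- if (is.null(quality$duration_tol)) 0.30 else quality$duration_tol
  min_rom <- if (is.null(quality$min_rom_deg)) 5 else quality$min_rom_deg
  cyc <- rbind(as.data.frame(left), as.data.frame(right))
  out0 <- data.frame(t_start = numeric(), t_end = numeric(),
                     left_t_ic = numeric(), right_t_ic = numeric(),
                     initiating_limb = character(),
                     initiating_confident = logical(),
                     quality = character(), reject_reason = character(),
                     stringsAsFactors = FALSE)
  if (nrow(cyc) == 0L || nrow(as.data.frame(left)) == 0L ||
      nrow(as.data.frame(right)) == 0L)
    return(structure(out0, class = c("cycle_pairs", "data.frame")))
  cyc <- cyc[order(cyc$t_ic), , drop = FALSE]
  med_dur <- stats::median(cyc$duration)
  rows <- list()
  i <- 1L
  while (i < nrow(cyc)) {
    a <- cyc[i, ]; b <- cyc[i + 1L, ]
    if (a$limb == b$limb) { i <- i + 1L; next }  # missed contralateral stride
    lft <- if (a$limb == "left") a else b
    rgt <- if (a$limb == "left") b else a
    # the two cycles of a pair must overlap in time
    if (min(lft$t_end, rgt$t_end) <= max(lft$t_ic, rgt$t_ic)) {
      i <- i + 1L; next
    }
    reasons <- character(0)
    for (cc in list(lft, rgt)) {
      if (abs(cc$duration - med_dur) > dur_tol * med_dur)
        reasons <- c(reasons, sprintf("%s duration %.2fs deviates >%.0f%% from median %.2fs",
                                      cc$limb, cc$duration, 100 * dur_tol, med_dur))
      if (cc$rom_deg < min_rom)
        reasons <- c(reasons, sprintf("%s sagittal ROM %.1f deg < %.1f deg",
                                      cc$limb, cc$rom_deg, min_rom))
    }
    init <- if (!is.null(pelvic_yaw))
      determine_initiating_limb(pelvic_yaw, lft, rgt)
    else list(limb = a$limb, confident = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      t_start = a$t_ic, t_end = max(lft$t_end, rgt$t_end),
      left_t_ic = lft$t_ic, right_t_ic = rgt$t_ic,
      initiating_limb = init$limb, initiating_confident = init$confident,
      quality = if (length(reasons)) "rejected" else "accepted",
      reject_reason = if (length(reasons)) paste(reasons, collapse = "; ")
        else NA_character_,
      stringsAsFactors = FALSE
    )
    i <- i + 2L
  }
  out <- if (length(rows)) do.call(rbind, rows) else out0
  # an accepted cycle left over at the end of the walk contributes one step
  terminal <- FALSE
  t_last <- if (any(out$quality == "accepted"))
    max(out$t_end[out$quality == "accepted"]) else NA_real_
  if (i == nrow(cyc)) {
    cc <- cyc[i, ]
    terminal <- abs(cc$duration - med_dur) <= dur_tol * med_dur &&
      cc$rom_deg >= min_rom
    if (terminal) t_last <- max(t_last, cc$t_end, na.rm = TRUE)
  }
  structure(out, terminal_unpaired = terminal, t_last_end = t_last,
            class = c("cycle_pairs", "data.frame"))
}

#' Resample one cycle's angle trace onto the 0-100% grid
#'
#' Linear interpolation of the chosen plane's angle onto 101 equally spaced
#' points spanning the cycle (0, 1, ..., 100% of its duration), removing the
#' dependence on absolute cycle time.
#'
#' @param angles an [orientation_series()].
#' @param cycle one row of a `gait_cycles` table (or a list with `t_ic`,
#'   `t_end`).
#' @param plane `"sagittal"`, `"frontal"` or `"transverse"`.
#' @return numeric vector of length 101.
#' @export
normalize_cycle <- function(angles, cycle, plane = "sagittal") {
  plane <- match.arg(plane, names(plane_to_angle))
  if (cycle$t_ic < min(angles$t) - 1e-9 || cycle$t_end > max(angles$t) + 1e-9)
    stop("bounds error: cycle [", cycle$t_ic, ", ", cycle$t_end,
         "] outside the series support")
  grid <- seq(cycle$t_ic, cycle$t_end, length.out = 101L)
  stats::approx(angles$t, angles[[plane_to_angle[[plane]]]], xout = grid,
                rule = 2L)$y
}

#' Pointwise mean and SD profile over normalized cycles
#'
#' @param cycles list of 101-point vectors from [normalize_cycle()].
#' @param plane,placement labels carried into the result.
#' @return object of class `normalized_profile`: list with `grid` (0..100),
#'   `mean_deg`, `sd_deg` (n-1 denominator; all zero when a single cycle),
#'   `n_cycles`, `plane`, `placement`.
#' @export
profile_stats <- function(cycles, plane = "sagittal", placement = "left_shank") {
  if (length(cycles) == 0L)
    stop("insufficient-data error: no cycles to average")
  m <- do.call(cbind, cycles)
  if (nrow(m) != 101L) stop("profiles must have 101 points")
  mean_deg <- rowMeans(m)
  sd_deg <- if (ncol(m) == 1L) rep(0, 101L) else apply(m, 1L, stats::sd)
  structure(list(grid = 0:100, mean_deg = mean_deg, sd_deg = sd_deg,
                 n_cycles = ncol(m), plane = plane, placement = placement),
            class = "normalized_profile")
}

#' @export
print.normalized_profile <- function(x, ...) {
  cat(sprintf("<normalized_profile> %s %s, n = %d cycles, mean ROM %.1f deg\n",
              x$placement, x$plane, x$n_cycles, diff(range(x$mean_deg))))
  invisible(x)
}
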