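#' Course geometry of the walk test
#'
#' The six-minute walk test is conducted on a straight, level course; the
#' default straight length is 32 m, with 180-degree turns at each end.
#'
#' @param straight_length_m length of the straight, meters.
#' @param turn_angle_deg turn magnitude, degrees.
#' @return a `course_model` list.
#' @export
course_model <- function(straight_length_m = 32, turn_angle_deg = 180) {
  if (straight_length_m <= 0) stop("straight_length_m must be positive")
  structure(list(straight_length_m = straight_length_m,
                 turn_angle_deg = turn_angle_deg),
            class = "course_model")
}

#' Count steps from accepted cycle pairs
#'
#' Each accepted stride pair contributes two steps; an accepted unpaired
#' cycle at the end of the walk (the terminal contact has no contralateral
#' partner) contributes one more.
#'
#' @param pairs a `cycle_pairs` table from [pair_and_filter()].
#' @return integer step count (0 for empty input).
#' @export
count_steps <- function(pairs) {
  n <- if (nrow(pairs)) sum(pairs$quality == "accepted") else 0L
  2L * n + as.integer(isTRUE(attr(pairs, "terminal_unpaired")))
}

#' Detect 180-degree turns from pelvic yaw
#'
#' Walking the course reverses heading by ~180 degrees at each end. The
#' pelvic yaw is unwrapped to a cumulative heading, smoothed with a moving
#' average that suppresses the step-frequency oscillation, and a turn is
#' reported at the midpoint of every monotone excursion accumulating at
#' least `min_turn_frac` of the nominal turn angle.
#'
#' @param pelvic_yaw sacrum [orientation_series()].
#' @param course a [course_model()].
#' @param smooth_s moving-average width, seconds (should exceed one stride).
#' @param min_turn_frac fraction of the turn angle that must accumulate.
#' @return numeric vector of turn times, seconds (possibly empty).
#' @export
detect_turns <- function(pelvic_yaw, course = course_model(), smooth_s = 1.5,
                         min_turn_frac = 0.6) {
  t <- pelvic_yaw$t
  y <- pelvic_yaw$yaw
  n <- length(t)
  if (n < 5L) return(numeric(0))
  h <- unwrap_deg(y)   # cumulative heading
  dt <- stats::median(diff(t))
  w <- max(3L, round(smooth_s / dt))
  if (w %% 2L == 0L) w <- w + 1L
  hs <- stats::filter(h, rep(1 / w, w), sides = 2L)
  hs <- as.numeric(hs)
  # extend the ends so edge turns are not lost
  hs[is.na(hs)] <- h[is.na(hs)]
  thresh <- min_turn_frac * course$turn_angle_deg
  turns <- numeric(0)
  # walk through monotone runs of the smoothed heading
  dh <- diff(hs)
  sgn <- sign(dh)
  sgn[sgn == 0] <- NA
  run_start <- 1L
  i <- 2L
  cur <- sgn[1L]
  flush <- function(a, b) {
    if (abs(hs[b] - hs[a]) >= thresh) {
      mid <- (hs[a] + hs[b]) / 2
      # turn time = where the heading crosses the midpoint of the excursion
      seg <- a:b
      k <- which.min(abs(hs[seg] - mid))
      t[seg[k]]
    } else NA_real_
  }
  for (i in seq_along(sgn)) {
    s <- sgn[i]
    if (is.na(s)) next
    if (is.na(cur)) { cur <- s; run_start <- i; next }
    if (s != cur) {
      tt <- flush(run_start, i)
      if (!is.na(tt)) turns <- c(turns, tt)
      run_start <- i
      cur <- s
    }
  }
  tt <- flush(run_start, length(hs))
  if (!is.na(tt)) turns <- c(turns, tt)
  sort(turns)
}

#' Summary metrics of a six-minute walk
#'
#' Distance is derived from the known course geometry: each detected turn
#' marks one completed straight, and the partial final straight is estimated
#' from the per-straight step count (steps after the last turn, scaled by
#' the average steps per completed straight). This avoids double-integrating
#' acceleration, which drifts. Speed uses the full test duration, per field
#' convention.
#'
#' @param pairs `cycle_pairs` from [pair_and_filter()].
#' @param turns turn times from [detect_turns()].
#' @param course a [course_model()].
#' @param duration_s test duration, seconds (360 for the 6MWT).
#' @return object of class `walk_metrics`: list with `distance_m`,
#'   `step_count`, `avg_step_length_m`, `mean_speed_kmh`, `n_turns`.
#' @export
walk_metrics <- function(pairs, turns, course = course_model(),
                         duration_s = 360) {
  if (duration_s <= 0) stop("duration_s must be positive")
  steps <- count_steps(pairs)
  n_turns <- length(turns)
  if (steps == 0L && n_turns > 0L)
    stop("inconsistency error: turns detected but no steps")
  acc <- pairs[pairs$quality == "accepted", , drop = FALSE]
  t_last <- attr(pairs, "t_last_end")
  if (is.null(t_last) || is.na(t_last))
    t_last <- if (nrow(acc)) max(acc$t_end) else NA_real_
  if (n_turns > 0L && nrow(acc)) {
    # one straight per turn; the partial final straight is walked at the
    # session's pace, estimated from the per-straight traversal time
    t_first <- min(acc$t_start)
    straight_time <- if (n_turns >= 2L) mean(diff(turns))
      else turns[1L] - t_first
    partial <- if (straight_time > 0)
      min(course$straight_length_m,
          course$straight_length_m *
            max(0, t_last - turns[n_turns]) / straight_time) else 0
    distance <- n_turns * course$straight_length_m + partial
  } else {
    # no completed straight: course-based distance is unknown
    distance <- 0
  }
  structure(list(
    distance_m = distance,
    step_count = steps,
    avg_step_length_m = if (steps > 0L) distance / steps else 0,
    mean_speed_kmh = distance / duration_s * 3.6,
    n_turns = n_turns
  ), class = "walk_metrics")
}

#' @export
print.walk_metrics <- function(x, ...) {
  cat(sprintf(
    "<walk_metrics> %.1f m in %d steps (%.3f m/step), %.2f km/h, %d turns\n",
    x$distance_m, x$step_count, x$avg_step_length_m, x$mean_speed_kmh,
    x$n_turns))
  invisible(x)
}

#' Mean angles over the first straight gait segment of a minute
#'
#' For reliability analysis the test is sampled at minutes 1, 3 and 6: the
#' first dynamic, turn-free interval of at least `min_len_s` seconds
#' beginning at or after the minute boundary is located, and each
#' plane/placement angle is averaged over it.
#'
#' @param angles named list of zero-referenced [orientation_series()] per
#'   placement (`left_shank`, `right_shank`, `sacrum`).
#' @param segments `activity_segments` from [classify_activity()].
#' @param turns turn times from [detect_turns()].
#' @param minute 1, 3 or 6.
#' @param t_origin time of the test start (default: start of the first
#'   dynamic segment), so minute m spans
#'   `[t_origin + (m-1)*60, t_origin + m*60)`.
#' @param min_len_s minimum straight-segment length, seconds.
#' @param turn_halfwidth_s half-width of the exclusion zone around a turn.
#' @return object of class `minute_snapshot`: data frame with columns
#'   `minute`, `placement`, `plane`, `mean_deg`, `t_start`, `t_end`; or
#'   `NULL` (with a message) when the minute has no straight segment.
#' @export
minute_snapshot <- function(angles, segments, turns, minute,
                            t_origin = NULL, min_len_s = 5,
                            turn_halfwidth_s = 2) {
  if (!minute %in% c(1, 3, 6)) stop("minute must be 1, 3 or 6")
  dyn <- segments[segments$label == "dynamic", , drop = FALSE]
  if (is.null(t_origin)) {
    if (nrow(dyn) == 0L) return(NULL)
    t_origin <- dyn$t_start[1L]
  }
  m_lo <- t_origin + (minute - 1) * 60
  m_hi <- t_origin + minute * 60
  # carve turn-free intervals out of the dynamic segments
  interval <- NULL
  for (i in seq_len(nrow(dyn))) {
    lo <- max(dyn$t_start[i], m_lo)
    hi <- dyn$t_end[i]
    if (hi <= m_lo) next
    cuts <- sort(turns[turns > lo - turn_halfwidth_s & turns < hi + turn_halfwidth_s])
    edges <- c(lo, as.vector(rbind(cuts - turn_halfwidth_s,
                                   cuts + turn_halfwidth_s)), hi)
    for (j in seq(1L, length(edges) - 1L, by = 2L)) {
      a <- max(edges[j], lo); b <- min(edges[j + 1L], hi)
      if (a >= m_lo && a < m_hi && b - a >= min_len_s) {
        interval <- c(a, b); break
      }
    }
    if (!is.null(interval)) break
  }
  if (is.null(interval)) {
    message("no straight gait segment of >= ", min_len_s,
            " s found in minute ", minute)
    return(NULL)
  }
  rows <- list()
  for (p in names(angles)) {
    s <- angles[[p]]
    sel <- s$t >= interval[1L] & s$t < interval[2L]
    for (pl in names(plane_to_angle)) {
      rows[[length(rows) + 1L]] <- data.frame(
        minute = minute, placement = p, plane = pl,
        mean_deg = mean(s[[plane_to_angle[[pl]]]][sel]),
        t_start = interval[1L], t_end = interval[2L],
        stringsAsFactors = FALSE)
    }
  }
  structure(do.call(rbind, rows),
            class = c("minute_snapshot", "data.frame"))
}
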