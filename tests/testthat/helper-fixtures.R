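# Programmatic fixtures shared across test files.

make_static_stream <- function(duration_s = 10, rate = 60, gyro = c(0, 0, 0),
                               placement = "left_shank",
                               acc = c(0, 0, 1), mag = c(0.22, 0, -0.41)) {
  t <- seq(0, duration_s, by = 1 / rate)
  n <- length(t)
  sensor_stream(t,
                matrix(rep(acc, each = n), n),
                matrix(rep(gyro, each = n), n),
                matrix(rep(mag, each = n), n),
                placement = placement, rate_hz = rate)
}

# orientation series built directly from simulator ground-truth quaternions
truth_orientation <- function(sim, placement) {
  orientation_series(sim$truth$t, sim$truth$quat[[placement]], placement)
}

# a small, fast walking session reused by several files (computed once)
shared_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_session(gait_sim_config(duration_s = 60, seed = 5))
    cache
  }
})

shared_analysis <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- suppressMessages(analyze_session(shared_sim()$set))
    cache
  }
})

make_cycles_df <- function(t_ic, limb = "left", duration = NULL, rom = 20) {
  duration <- if (is.null(duration)) diff(c(t_ic, t_ic[length(t_ic)] + 1))
    else rep_len(duration, length(t_ic))
  structure(
    data.frame(limb = limb, t_ic = t_ic, t_end = t_ic + duration,
               duration = duration, rom_deg = rom,
               quality = "accepted", reject_reason = NA_character_,
               stringsAsFactors = FALSE),
    class = c("gait_cycles", "data.frame"))
}
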