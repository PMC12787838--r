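#' Simulate a repeated-measures matrix with a known intraclass correlation
#'
#' Draws from the one-way random-effects model
#' `x_{sj} = mean + b_s + e_{sj}` with `Var(b) = icc * sd^2` and
#' `Var(e) = (1 - icc) * sd^2`, so the population one-way single-measure ICC
#' equals `icc` by construction.
#'
#' @param n_subjects,k matrix dimensions.
#' @param icc target population ICC in `[0, 1)`.
#' @param mean,sd marginal mean and SD of a single measurement.
#' @return a [repeated_measures()] matrix.
#' @export
simulate_repeated_measures <- function(n_subjects, k = 3, icc = 0.8,
                                       mean = 0, sd = 1) {
  if (icc < 0 || icc >= 1) stop("config error: icc must lie in [0, 1)")
  b <- stats::rnorm(n_subjects, 0, sd * sqrt(icc))
  e <- matrix(stats::rnorm(n_subjects * k, 0, sd * sqrt(1 - icc)),
              n_subjects, k)
  repeated_measures(mean + b + e)
}

# Group presets: the control-like group walks faster with a fuller sagittal
# excursion; the research-like (pre-arthroplasty) group is slowed and
# flattened. Cadence presets put the mean 6-min step count at 595 (control)
# and 512 (research).
cohort_group_presets <- function(group) {
  switch(group,
    CG = list(cadence_spm = 595 / 6, step_length_m = 0.6,
              shank_sagittal_rom_deg = 20, pelvic_tilt_deg = 21.5),
    RG = list(cadence_spm = 512 / 6, step_length_m = 0.58,
              shank_sagittal_rom_deg = 14, pelvic_tilt_deg = 21.5),
    stop("unknown group: ", group)
  )
}

# Per-row mean and between-minute SD of the nine reliability parameters
# (plane x body part), used when drawing per-minute snapshot angles.
cohort_angle_rows <- function() {
  data.frame(
    plane = rep(c("frontal", "sagittal", "transverse"), each = 3L),
    part = rep(c("left_leg", "right_leg", "pelvis"), times = 3L),
    mean = c(-0.12, 0.73, 0.02, 7.56, 7.26, 21.51, -1.62, 1.59, 0.01),
    sd = c(3.33, 4.64, 1.18, 3.46, 3.38, 7.94, 9.56, 7.16, 0.21),
    stringsAsFactors = FALSE
  )
}

#' Simulate a cohort of walk-test subjects
#'
#' Subject-level gait parameters (cadence, step length, sagittal ROM,
#' pelvic tilt) are drawn from group distributions; per-minute snapshot
#' angles for the nine plane x body-part parameters are drawn from the
#' one-way random-effects model with minute-to-minute correlation
#' `within_subject_rho`, so reliability statistics computed downstream have
#' a known population target.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param group `"CG"` (control-like) or `"RG"` (research-like, slowed and
#'   flattened gait).
#' @param between_subject_sd named list of SDs for the subject-level draws
#'   (`cadence_spm`, `step_length_m`, `shank_sagittal_rom_deg`,
#'   `pelvic_tilt_deg`).
#' @param within_subject_rho target minute-to-minute ICC of the snapshot
#'   angles, in `[0, 1)`.
#' @param seed integer seed.
#' @param signals if `TRUE`, also run [simulate_session()] per subject
#'   (expensive); otherwise only the parameter tables are returned and
#'   `$configs` holds one ready-to-run [gait_sim_config()] per subject.
#' @param duration_s walk duration passed to the per-subject configs.
#' @return list of class `gait_cohort`: `subjects` (true parameter table),
#'   `minute_values` (subject x minute x plane x part snapshot angles, the
#'   input for [reliability_table()] via its `subject/minute/plane/part/value`
#'   columns), `configs`, and `sessions` (when `signals = TRUE`).
#' @export
simulate_cohort <- function(n_subjects, group = c("CG", "RG"),
                            between_subject_sd = list(
                              cadence_spm = 7, step_length_m = 0.05,
                              shank_sagittal_rom_deg = 2.5,
                              pelvic_tilt_deg = 7.9),
                            within_subject_rho = 0.8, seed = 1,
                            signals = FALSE, duration_s = 360) {
  if (n_subjects < 2L) stop("config error: need at least 2 subjects")
  if (within_subject_rho < 0 || within_subject_rho >= 1)
    stop("config error: within_subject_rho must lie in [0, 1)")
  group <- match.arg(group)
  set.seed(seed)
  preset <- cohort_group_presets(group)
  ids <- sprintf("%s%02d", tolower(group), seq_len(n_subjects))
  subjects <- data.frame(
    subject = ids,
    cadence_spm = pmax(40, stats::rnorm(n_subjects, preset$cadence_spm,
                                        between_subject_sd$cadence_spm)),
    step_length_m = pmax(0.2, stats::rnorm(n_subjects, preset$step_length_m,
                                           between_subject_sd$step_length_m)),
    shank_sagittal_rom_deg = pmax(6, stats::rnorm(
      n_subjects, preset$shank_sagittal_rom_deg,
      between_subject_sd$shank_sagittal_rom_deg)),
    pelvic_tilt_deg = stats::rnorm(n_subjects, preset$pelvic_tilt_deg,
                                   between_subject_sd$pelvic_tilt_deg),
    stringsAsFactors = FALSE
  )
  subjects$step_count_true <- round(subjects$cadence_spm * duration_s / 60)
  subjects$distance_true_m <- subjects$step_count_true * subjects$step_length_m

  rows <- cohort_angle_rows()
  mv <- list()
  for (r in seq_len(nrow(rows))) {
    b <- stats::rnorm(n_subjects, 0, rows$sd[r] * sqrt(within_subject_rho))
    for (m in c(1, 3, 6)) {
      e <- stats::rnorm(n_subjects, 0, rows$sd[r] * sqrt(1 - within_subject_rho))
      mv[[length(mv) + 1L]] <- data.frame(
        subject = ids, minute = m, plane = rows$plane[r], part = rows$part[r],
        value = rows$mean[r] + b + e, stringsAsFactors = FALSE)
    }
  }
  minute_values <- do.call(rbind, mv)

  configs <- lapply(seq_len(n_subjects), function(i) {
    gait_sim_config(
      cadence_spm = subjects$cadence_spm[i],
      step_length_m = subjects$step_length_m[i],
      duration_s = duration_s,
      shank_sagittal_rom_deg = subjects$shank_sagittal_rom_deg[i],
      pelvic_tilt_deg = subjects$pelvic_tilt_deg[i],
      seed = seed * 1000L + i
    )
  })
  names(configs) <- ids
  sessions <- NULL
  if (signals)
    sessions <- lapply(seq_len(n_subjects), function(i)
      simulate_session(configs[[i]], subject_id = ids[i]))
  structure(list(subjects = subjects, minute_values = minute_values,
                 configs = configs, sessions = sessions, group = group,
                 within_subject_rho = within_subject_rho, seed = seed),
            class = "gait_cohort")
}

#' @export
print.gait_cohort <- function(x, ...) {
  cat(sprintf("<gait_cohort> %s, n = %d, target minute-to-minute ICC %.2f%s\n",
              x$group, nrow(x$subjects), x$within_subject_rho,
              if (is.null(x$sessions)) "" else ", with simulated signals"))
  invisible(x)
}
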