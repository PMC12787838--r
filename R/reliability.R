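#' Repeated-measures matrix
#'
#' Subjects x k matrix of one gait parameter measured k times (here: the
#' minute-1, minute-3 and minute-6 snapshots of the walk test, so k = 3).
#' Subjects with missing measurements must be dropped before construction
#' (listwise deletion); the constructor refuses missing cells.
#'
#' @param values numeric matrix or data frame, one row per subject, one
#'   column per repeated measurement.
#' @param subject_ids optional row labels.
#' @return a `repeated_measures` matrix.
#' @export
repeated_measures <- function(values, subject_ids = NULL) {
  m <- as.matrix(values)
  storage.mode(m) <- "double"
  if (nrow(m) < 2L) stop("at least 2 subjects are required")
  if (ncol(m) < 2L) stop("at least 2 repeated measurements are required")
  if (any(!is.finite(m))) stop("missing or non-finite cells: drop incomplete subjects first")
  rownames(m) <- if (is.null(subject_ids)) paste0("s", seq_len(nrow(m))) else subject_ids
  structure(m, class = c("repeated_measures", class(m)))
}

as_rm <- function(m) {
  if (inherits(m, "repeated_measures")) m else repeated_measures(m)
}

#' One-way ANOVA variance decomposition with subjects as the factor
#'
#' Decomposes a subjects x k repeated-measures matrix into between-subject
#' and within-subject mean squares (degrees of freedom n-1 and n(k-1)), and
#' additionally reports the per-item (column) variances and the variance of
#' the per-subject total scores (both with n-1 denominators), the
#' ingredients of Cronbach's alpha.
#'
#' @param m a [repeated_measures()] matrix (or coercible).
#' @return list of class `variance_decomposition` with `ms_between`,
#'   `ms_within`, `df_between`, `df_within`, `s_i_sq`, `s_c_sq`, `n`, `k`,
#'   and `degenerate` (TRUE when the matrix is constant).
#' @export
variance_decomposition <- function(m) {
  m <- as_rm(m)
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  rm_ <- rowMeans(m)
  ss_between <- k * sum((rm_ - grand)^2)
  ss_within <- sum((m - rm_)^2)
  ms_between <- ss_between / (n - 1)
  ms_within <- ss_within / (n * (k - 1))
  structure(list(
    ms_between = ms_between, ms_within = ms_within,
    df_between = n - 1L, df_within = n * (k - 1L),
    s_i_sq = apply(m, 2L, stats::var),
    s_c_sq = stats::var(rowSums(m)),
    n = n, k = k,
    degenerate = ms_between == 0 && ms_within == 0
  ), class = "variance_decomposition")
}

#' Cronbach's alpha
#'
#' Internal consistency of k repeated measurements:
#' `alpha = k/(k-1) * (1 - sum(s_i^2) / s_c^2)`, where `s_i^2` are the item
#' (column) variances and `s_c^2` the variance of the per-subject totals.
#' May be negative; values of 1 indicate perfectly duplicated items.
#'
#' @inheritParams variance_decomposition
#' @return alpha (scalar).
#' @export
cronbach_alpha <- function(m) {
  m <- as_rm(m)
  d <- variance_decomposition(m)
  if (d$s_c_sq <= 0)
    stop("undefined-alpha error: total-score variance is zero")
  d$k / (d$k - 1) * (1 - sum(d$s_i_sq) / d$s_c_sq)
}

#' One-way single-measure intraclass correlation coefficient
#'
#' ICC(1,1): `(MS_between - MS_within) / (MS_between + (k-1) * MS_within)`
#' from the one-way ANOVA with subjects as the random factor. Equals 1 when
#' all within-subject variation vanishes, and `-1/(k-1)` when there is no
#' between-subject variance.
#'
#' @inheritParams variance_decomposition
#' @return ICC (scalar in `[-1/(k-1), 1]`).
#' @export
icc_oneway <- function(m) {
  m <- as_rm(m)
  d <- variance_decomposition(m)
  if (d$degenerate)
    stop("undefined-ICC error: matrix has no variance at all")
  (d$ms_between - d$ms_within) / (d$ms_between + (d$k - 1) * d$ms_within)
}

#' Qualitative ICC band
#'
#' Standard reliability interpretation: below 0.5 poor, 0.5 to 0.75
#' moderate, 0.75 to 0.90 good, 0.90 and above excellent (boundaries
#' inclusive toward the higher band).
#'
#' @param icc numeric vector of ICC values (each <= 1).
#' @return character vector of bands.
#' @export
band_icc <- function(icc) {
  stopifnot(all(icc <= 1 + 1e-12))
  cut(icc, breaks = c(-Inf, 0.5, 0.75, 0.90, Inf), right = FALSE,
      labels = c("poor", "moderate", "good", "excellent")) |> as.character()
}

#' Qualitative Cronbach's alpha band
#'
#' Conventional internal-consistency interpretation: below 0.6 poor, 0.6 to
#' 0.7 questionable, 0.7 to 0.8 acceptable, 0.8 to 0.9 good, 0.9 and above
#' excellent (boundaries inclusive toward the higher band).
#'
#' @param alpha numeric vector of alpha values (each <= 1).
#' @return character vector of bands.
#' @export
band_alpha <- function(alpha) {
  stopifnot(all(alpha <= 1 + 1e-12))
  cut(alpha, breaks = c(-Inf, 0.6, 0.7, 0.8, 0.9, Inf), right = FALSE,
      labels = c("poor", "questionable", "acceptable", "good", "excellent")) |>
    as.character()
}

#' Cohen's d
#'
#' Standardized mean difference `(mean_a - mean_b) / s_pooled`, with the
#' pooled SD weighted by the group degrees of freedom (n-1).
#'
#' @param group_a,group_b numeric vectors, each of length >= 2.
#' @return d (scalar).
#' @export
cohens_d <- function(group_a, group_b) {
  na <- length(group_a); nb <- length(group_b)
  if (na < 2L || nb < 2L) stop("each group needs at least 2 values")
  sp2 <- ((na - 1) * stats::var(group_a) + (nb - 1) * stats::var(group_b)) /
    (na + nb - 2)
  if (sqrt(sp2) < 1e-12)
    stop("undefined-d error: pooled SD is (numerically) zero")
  (mean(group_a) - mean(group_b)) / sqrt(sp2)
}

#' Fit the reliability model to a repeated-measures matrix
#'
#' The classic entry point: takes the subjects x k matrix of one parameter,
#' runs the one-way ANOVA decomposition and returns the fitted reliability
#' object carrying alpha, the one-way single-measure ICC, and their
#' qualitative bands.
#'
#' @inheritParams variance_decomposition
#' @return object of class `reliability_fit` with elements `mean`, `sd`
#'   (pooled over all subject-measurement values), `alpha`, `icc`,
#'   `alpha_band`, `icc_band`, `decomposition`, `n`, `k`.
#' @export
reliability <- function(m) {
  m <- as_rm(m)
  d <- variance_decomposition(m)
  alpha <- cronbach_alpha(m)
  icc <- icc_oneway(m)
  structure(list(
    mean = mean(m), sd = stats::sd(as.vector(m)),
    alpha = alpha, icc = icc,
    alpha_band = band_alpha(alpha), icc_band = band_icc(icc),
    decomposition = d, n = d$n, k = d$k
  ), class = "reliability_fit")
}

#' @export
print.reliability_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Reliability of %d repeated measurements on %d subjects\n",
              x$k, x$n))
  cat(sprintf("  mean (SD): %.*f (%.*f)\n", digits, x$mean, digits, x$sd))
  cat(sprintf("  Cronbach's alpha: %.*f (%s)\n", digits, x$alpha, x$alpha_band))
  cat(sprintf("  ICC(1,1):        %.*f (%s)\n", digits, x$icc, x$icc_band))
  invisible(x)
}

#' @export
summary.reliability_fit <- function(object, ...) {
  d <- object$decomposition
  cat("One-way ANOVA decomposition (subjects as factor)\n")
  cat(sprintf("  MS between: %.6g on %d df\n", d$ms_between, d$df_between))
  cat(sprintf("  MS within:  %.6g on %d df\n", d$ms_within, d$df_within))
  cat(sprintf("  item variances: %s\n",
              paste(signif(d$s_i_sq, 4), collapse = ", ")))
  cat(sprintf("  total-score variance: %.6g\n", d$s_c_sq))
  print(object)
  invisible(object)
}

#' @export
coef.reliability_fit <- function(object, ...) {
  c(alpha = object$alpha, icc = object$icc)
}

#' Reliability table over planes and body parts
#'
#' Builds the 9-row reliability table (3 planes x left leg / right leg /
#' pelvis) from per-subject minute snapshots: for each plane and part the
#' subjects' minute-1/3/6 values form the repeated-measures matrix, and the
#' row reports the pooled mean and SD, Cronbach's alpha, the one-way ICC and
#' their bands. Subjects missing any minute are dropped listwise per row
#' (with the dropped count recorded).
#'
#' @param snapshots data frame with columns `subject`, `minute` (1/3/6),
#'   `plane`, `part` (`left_leg`, `right_leg`, `pelvis`) and `value`
#'   (degrees). The helper [snapshots_from_minutes()] builds this from
#'   pipeline output.
#' @return data frame of class `reliability_table` with columns `plane`,
#'   `part`, `n`, `n_dropped`, `mean`, `sd`, `alpha`, `icc`, `alpha_band`,
#'   `icc_band`, `flag`. Rows with fewer than 2 complete subjects, or no
#'   between-subject variance, are flagged and carry NA statistics.
#' @export
reliability_table <- function(snapshots) {
  needed <- c("subject", "minute", "plane", "part", "value")
  if (!all(needed %in% names(snapshots)))
    stop("snapshots must have columns ", paste(needed, collapse = ", "))
  planes <- c("frontal", "sagittal", "transverse")
  parts <- c("left_leg", "right_leg", "pelvis")
  minutes <- sort(unique(snapshots$minute))
  rows <- list()
  for (pl in planes) for (pt in parts) {
    sub <- snapshots[snapshots$plane == pl & snapshots$part == pt, , drop = FALSE]
    wide <- stats::reshape(sub[, c("subject", "minute", "value")],
                           idvar = "subject", timevar = "minute",
                           direction = "wide")
    val_cols <- setdiff(names(wide), "subject")
    complete <- stats::complete.cases(wide[, val_cols, drop = FALSE])
    n_dropped <- sum(!complete)
    wide <- wide[complete, , drop = FALSE]
    base <- data.frame(plane = pl, part = pt, n = nrow(wide),
                       n_dropped = n_dropped, mean = NA_real_, sd = NA_real_,
                       alpha = NA_real_, icc = NA_real_,
                       alpha_band = NA_character_, icc_band = NA_character_,
                       flag = NA_character_, stringsAsFactors = FALSE)
    if (nrow(wide) < 2L || length(val_cols) < 2L) {
      base$flag <- "insufficient: fewer than 2 complete subjects"
    } else {
      mat <- as.matrix(wide[, val_cols, drop = FALSE])
      base$mean <- mean(mat); base$sd <- stats::sd(as.vector(mat))
      fit <- tryCatch(reliability(mat), error = function(e) e)
      if (inherits(fit, "error")) {
        base$flag <- conditionMessage(fit)
      } else {
        base$alpha <- fit$alpha; base$icc <- fit$icc
        base$alpha_band <- fit$alpha_band; base$icc_band <- fit$icc_band
      }
    }
    rows[[length(rows) + 1L]] <- base
  }
  structure(do.call(rbind, rows),
            class = c("reliability_table", "data.frame"))
}

#' Assemble the reliability-table input from analyzed sessions
#'
#' Maps the pipeline's per-minute snapshots (placement labels) onto the
#' body-part labels of the reliability table.
#'
#' @param per_subject named list: per subject, a data frame of minute
#'   snapshots (columns `minute`, `placement`, `plane`, `mean_deg`).
#' @return data frame with columns `subject`, `minute`, `plane`, `part`,
#'   `value` suitable for [reliability_table()].
#' @export
snapshots_from_minutes <- function(per_subject) {
  part_of <- c(left_shank = "left_leg", right_shank = "right_leg",
               sacrum = "pelvis")
  rows <- list()
  for (sid in names(per_subject)) {
    sn <- per_subject[[sid]]
    if (is.null(sn) || nrow(sn) == 0L) next
    rows[[length(rows) + 1L]] <- data.frame(
      subject = sid, minute = sn$minute, plane = sn$plane,
      part = unname(part_of[sn$placement]), value = sn$mean_deg,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no snapshots supplied")
  do.call(rbind, rows)
}

#' Published reliability coefficients of the instrument
#'
#' The nine reliability coefficients (Cronbach's alpha and one-way ICC per
#' plane and body part) reported in the instrument's clinical validation
#' study of the 6MWT in women with knee osteoarthritis, bundled as a worked
#' example for the banding functions.
#'
#' @return data frame with columns `plane`, `part`, `mean`, `sd`, `alpha`,
#'   `icc`.
#' @export
reference_reliability <- function() {
  path <- system.file("extdata", "reference_reliability.csv",
                      package = "imugait", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
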