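#' Raw inertial sensor streams
#'
#' A `sensor_stream` holds the time series recorded by one 9-DOF inertial
#' sensor (tri-axial accelerometer, gyroscope and magnetometer) at a fixed
#' body placement. Units are fixed at the boundary: seconds, g, degrees per
#' second and Gauss, matching the sensor's published full-scale ranges
#' (+/- 16 g, +/- 2000 deg/s, +/- 8 Gauss). Internally angular rates are
#' converted to rad/s where integration requires it.
#'
#' @param t numeric vector of sample times in seconds, strictly increasing.
#' @param acc,gyro,mag n x 3 numeric matrices (columns x, y, z) in g, deg/s
#'   and Gauss respectively.
#' @param placement one of `"left_shank"`, `"right_shank"`, `"sacrum"`.
#' @param rate_hz nominal sampling rate in Hz (60 by default; the sensor
#'   streams at 60 Hz in real time and logs at up to 120 Hz).
#'
#' @return An object of class `sensor_stream`: a data frame with columns
#'   `t`, `acc_x`, `acc_y`, `acc_z`, `gyro_x`, `gyro_y`, `gyro_z`,
#'   `mag_x`, `mag_y`, `mag_z` and attributes `placement` and `rate_hz`.
#' @export
sensor_stream <- function(t, acc, gyro, mag, placement, rate_hz = 60) {
  placement <- match.arg(placement, c("left_shank", "right_shank", "sacrum"))
  acc <- as.matrix(acc); gyro <- as.matrix(gyro); mag <- as.matrix(mag)
  n <- length(t)
  if (n == 0L) stop("sensor_stream: empty stream")
  if (nrow(acc) != n || nrow(gyro) != n || nrow(mag) != n)
    stop("sensor_stream: channel lengths disagree with time vector")
  df <- data.frame(
    t = as.numeric(t),
    acc_x = acc[, 1L], acc_y = acc[, 2L], acc_z = acc[, 3L],
    gyro_x = gyro[, 1L], gyro_y = gyro[, 2L], gyro_z = gyro[, 3L],
    mag_x = mag[, 1L], mag_y = mag[, 2L], mag_z = mag[, 3L]
  )
  structure(df, placement = placement, rate_hz = rate_hz,
            class = c("sensor_stream", "data.frame"))
}

sensor_csv_columns <- c(
  "t_s", "acc_x_g", "acc_y_g", "acc_z_g",
  "gyro_x_dps", "gyro_y_dps", "gyro_z_dps",
  "mag_x_gauss", "mag_y_gauss", "mag_z_gauss"
)

#' Validate a sensor stream against the physical data model
#'
#' Checks the sensor's full-scale ranges (|acc| <= 16 g, |gyro| <= 2000 deg/s,
#' |mag| <= 8 Gauss per axis), non-negative strictly increasing timestamps,
#' finiteness, and sampling regularity (at least 99% of inter-sample gaps
#' within +/- 20% of the nominal interval).
#'
#' @param stream a [sensor_stream()].
#' @return the stream, invisibly, if valid; otherwise an error naming the
#'   offending rows.
#' @export
validate_stream <- function(stream) {
  stopifnot(inherits(stream, "sensor_stream"))
  t <- stream$t
  if (t[1L] < 0) stop("validation error: negative timestamp at row 1")
  if (any(!is.finite(as.matrix(stream))))
    stop("validation error: non-finite values at rows ",
         paste(utils::head(which(!stats::complete.cases(stream) |
                                   !apply(is.finite(as.matrix(stream)), 1L, all)), 5L),
               collapse = ", "))
  if (length(t) > 1L && any(diff(t) <= 0))
    stop("validation error: timestamps not strictly increasing at rows ",
         paste(utils::head(which(diff(t) <= 0) + 1L, 5L), collapse = ", "))
  bad <- which(
    abs(stream$acc_x) > 16 | abs(stream$acc_y) > 16 | abs(stream$acc_z) > 16 |
    abs(stream$gyro_x) > 2000 | abs(stream$gyro_y) > 2000 | abs(stream$gyro_z) > 2000 |
    abs(stream$mag_x) > 8 | abs(stream$mag_y) > 8 | abs(stream$mag_z) > 8
  )
  if (length(bad))
    stop("validation error: sensor range exceeded at rows ",
         paste(utils::head(bad, 10L), collapse = ", "))
  if (length(t) > 2L) {
    dt <- diff(t)
    nominal <- 1 / attr(stream, "rate_hz")
    frac_ok <- mean(abs(dt - nominal) <= 0.2 * nominal)
    if (frac_ok < 0.99)
      stop("validation error: only ", round(100 * frac_ok, 1),
           "% of sampling intervals within 20% of nominal ", nominal, " s")
  }
  invisible(stream)
}

#' Read a raw sensor CSV
#'
#' The on-disk format is one CSV per placement with the fixed header
#' `t_s,acc_x_g,acc_y_g,acc_z_g,gyro_x_dps,gyro_y_dps,gyro_z_dps,mag_x_gauss,mag_y_gauss,mag_z_gauss`.
#' Rows that fail numeric parsing are an error (never skipped silently), as
#' are samples outside the sensor's physical ranges.
#'
#' @inheritParams sensor_stream
#' @param path path to the CSV file.
#' @return a validated [sensor_stream()].
#' @export
read_sensor_csv <- function(path, placement, rate_hz = 60) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  if (!identical(names(df), sensor_csv_columns))
    stop("format error: expected columns ", paste(sensor_csv_columns, collapse = ","),
         " but found ", paste(names(df), collapse = ","))
  num <- suppressWarnings(vapply(df, as.numeric, numeric(nrow(df))))
  if (nrow(df) == 1L) num <- matrix(num, nrow = 1L, dimnames = list(NULL, names(df)))
  bad <- which(apply(is.na(num), 1L, any))
  if (length(bad))
    stop("format error: non-numeric values at rows ",
         paste(utils::head(bad, 10L), collapse = ", "))
  s <- sensor_stream(
    t = num[, "t_s"],
    acc = num[, c("acc_x_g", "acc_y_g", "acc_z_g")],
    gyro = num[, c("gyro_x_dps", "gyro_y_dps", "gyro_z_dps")],
    mag = num[, c("mag_x_gauss", "mag_y_gauss", "mag_z_gauss")],
    placement = placement, rate_hz = rate_hz
  )
  validate_stream(s)
  s
}

#' Write a sensor stream to CSV
#'
#' Inverse of [read_sensor_csv()]; full double precision so that
#' write-then-read round-trips losslessly.
#'
#' @inheritParams validate_stream
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sensor_csv <- function(stream, path) {
  stopifnot(inherits(stream, "sensor_stream"))
  out <- as.data.frame(stream)
  names(out) <- sensor_csv_columns
  # format() keeps 17 significant digits -> exact double round-trip
  for (j in seq_along(out)) out[[j]] <- sprintf("%.17g", out[[j]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Extract a half-open time window from a stream
#'
#' Returns the samples with `t0 <= t < t1`. Half-open windows guarantee the
#' partition property: adjacent windows never share a sample.
#'
#' @inheritParams validate_stream
#' @param t0,t1 window bounds in seconds, `t0 < t1`.
#' @param rezero if `TRUE`, timestamps are re-zeroed to `t - t0` (off by
#'   default).
#' @return a [sensor_stream()] restricted to the window.
#' @export
slice_window <- function(stream, t0, t1, rezero = FALSE) {
  stopifnot(inherits(stream, "sensor_stream"))
  if (!(t0 < t1)) stop("slice_window: t0 must be < t1")
  keep <- stream$t >= t0 & stream$t < t1
  if (!any(keep)) stop("empty-window error: [", t0, ", ", t1,
                       ") does not intersect the stream support")
  out <- stream[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (rezero) out$t <- out$t - t0
  structure(out, placement = attr(stream, "placement"),
            rate_hz = attr(stream, "rate_hz"),
            class = c("sensor_stream", "data.frame"))
}

#' Bundle the three placements of one session
#'
#' @param left_shank,right_shank,sacrum [sensor_stream()] objects with the
#'   matching placement labels.
#' @param subject_id opaque subject label.
#' @return an object of class `sensor_set` (a named list of streams).
#' @export
sensor_set <- function(left_shank, right_shank, sacrum, subject_id = "anonymous") {
  streams <- list(left_shank = left_shank, right_shank = right_shank,
                  sacrum = sacrum)
  for (p in names(streams)) {
    if (!inherits(streams[[p]], "sensor_stream"))
      stop("sensor_set: ", p, " is not a sensor_stream")
    if (!identical(attr(streams[[p]], "placement"), p))
      stop("sensor_set: stream given for ", p, " is labelled ",
           attr(streams[[p]], "placement"))
  }
  supp <- vapply(streams, function(s) range(s$t), numeric(2L))
  if (max(supp[1L, ]) >= min(supp[2L, ]))
    stop("sensor_set: the three streams have no overlapping time support")
  structure(list(streams = streams, subject_id = subject_id),
            class = "sensor_set")
}

#' @export
print.sensor_stream <- function(x, ...) {
  cat(sprintf("<sensor_stream> %s, %d samples, %.1f s @ %g Hz nominal\n",
              attr(x, "placement"), nrow(x), diff(range(x$t)),
              attr(x, "rate_hz")))
  invisible(x)
}

#' @export
print.sensor_set <- function(x, ...) {
  cat(sprintf("<sensor_set> subject %s\n", x$subject_id))
  for (s in x$streams) print(s)
  invisible(x)
}
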