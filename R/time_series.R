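#' Uniformly sampled time series
#'
#' The basic container used throughout the package: a numeric channel sampled
#' at a fixed rate, with units and a time offset for the first sample.
#'
#' @param values Numeric vector of samples. Must be finite.
#' @param rate Sampling rate in Hz (> 0).
#' @param units Unit string, e.g. `"m/s^2"`, `"N"`, `"N.m"`.
#' @param t0 Time of the first sample in seconds.
#' @return An object of class `time_series`.
#' @examples
#' ts <- time_series(sin(seq(0, 2 * pi, length.out = 120)), rate = 120, units = "N")
#' ts_time(ts)[1:3]
#' @export
time_series <- function(values, rate, units = "", t0 = 0) {
  values <- as.numeric(values)
  if (length(values) < 1L) {
    stop("time_series: need at least one sample", call. = FALSE)
  }
  if (!all(is.finite(values))) {
    stop("time_series: values must be finite", call. = FALSE)
  }
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0) {
    stop("time_series: rate must be a positive scalar (Hz)", call. = FALSE)
  }
  structure(
    list(values = values, rate = as.numeric(rate),
         units = as.character(units), t0 = as.numeric(t0)),
    class = "time_series"
  )
}

#' @export
print.time_series <- function(x, ...) {
  cat(sprintf("<time_series> %d samples @ %g Hz [%s], t0 = %g s\n",
              length(x$values), x$rate, x$units, x$t0))
  invisible(x)
}

#' @export
length.time_series <- function(x) length(x$values)

#' Sample times of a time series
#' @param ts A `time_series`.
#' @return Numeric vector of sample times in seconds.
#' @export
ts_time <- function(ts) {
  stopifnot(inherits(ts, "time_series"))
  ts$t0 + (seq_along(ts$values) - 1) / ts$rate
}

#' Crop a time series to a sample-index range
#' @param ts A `time_series`.
#' @param from,to 1-based sample indices (inclusive).
#' @return The cropped `time_series`; `t0` advances accordingly.
#' @export
ts_crop <- function(ts, from, to) {
  stopifnot(inherits(ts, "time_series"))
  n <- length(ts$values)
  if (from < 1 || to > n || from > to) {
    stop("ts_crop: index range out of bounds", call. = FALSE)
  }
  time_series(ts$values[from:to], ts$rate, ts$units,
              t0 = ts$t0 + (from - 1) / ts$rate)
}

#' Bilateral wrist-IMU / handrim-kinetics recording
#'
#' Bundles the wrist IMU norm channels (linear acceleration, angular
#' velocity) with the handrim kinetic channels (Fx, Fy, Mz) for one side.
#' Kinetic channels may be absent in deployment mode (prediction-only).
#' Before alignment the IMU and kinetic channels may run at different rates;
#' [align_streams()] produces a recording on a single common rate.
#'
#' @param side `"left"` or `"right"`.
#' @param accel_norm `time_series`, norm of wrist linear acceleration (m/s^2).
#' @param gyro_norm `time_series`, norm of wrist angular velocity (rad/s).
#' @param fx,fy `time_series` of handrim reaction forces (N), or `NULL`.
#' @param mz `time_series` of the sagittal handrim moment (N.m), or `NULL`.
#' @return An object of class `wk_recording`.
#' @export
recording <- function(side, accel_norm, gyro_norm, fx = NULL, fy = NULL, mz = NULL) {
  side <- match.arg(side, c("left", "right"))
  stopifnot(inherits(accel_norm, "time_series"), inherits(gyro_norm, "time_series"))
  for (ch in list(fx, fy, mz)) {
    if (!is.null(ch)) stopifnot(inherits(ch, "time_series"))
  }
  if (length(accel_norm$values) != length(gyro_norm$values) ||
      accel_norm$rate != gyro_norm$rate) {
    stop("recording: IMU channels must share length and rate", call. = FALSE)
  }
  kin <- Filter(Negate(is.null), list(fx = fx, fy = fy, mz = mz))
  if (length(kin) > 1L) {
    n <- vapply(kin, function(ch) length(ch$values), integer(1))
    r <- vapply(kin, function(ch) ch$rate, numeric(1))
    if (length(unique(n)) != 1L || length(unique(r)) != 1L) {
      stop("recording: kinetic channels must share length and rate", call. = FALSE)
    }
  }
  structure(
    list(side = side, accel_norm = accel_norm, gyro_norm = gyro_norm,
         fx = fx, fy = fy, mz = mz),
    class = "wk_recording"
  )
}

#' @export
print.wk_recording <- function(x, ...) {
  cat(sprintf("<wk_recording> side = %s\n", x$side))
  cat(sprintf("  IMU: %d samples @ %g Hz\n",
              length(x$accel_norm$values), x$accel_norm$rate))
  if (!is.null(x$mz)) {
    cat(sprintf("  kinetics: %d samples @ %g Hz\n",
                length(x$mz$values), x$mz$rate))
  } else {
    cat("  kinetics: absent (deployment mode)\n")
  }
  invisible(x)
}

#' Does the recording carry measured kinetics?
#' @param rec A `wk_recording`.
#' @return `TRUE` when Fx, Fy and Mz are all present.
#' @export
has_kinetics <- function(rec) {
  stopifnot(inherits(rec, "wk_recording"))
  !is.null(rec$fx) && !is.null(rec$fy) && !is.null(rec$mz)
}

#' Synchronization events (handrim kicks)
#'
#' Sample indices of the two kick transients the subject produces at trial
#' start and end; used to align the kinetic and IMU streams.
#'
#' @param tc1,tc2 1-based sample indices, `tc1 < tc2`.
#' @param other Optional length-2 index pair of the same events located in a
#'   second channel (used to compute inter-stream offsets).
#' @return An object of class `sync_events`.
#' @export
sync_events <- function(tc1, tc2, other = NULL) {
  tc1 <- as.integer(tc1); tc2 <- as.integer(tc2)
  if (!(tc1 >= 1L && tc1 < tc2)) {
    stop("sync_events: need 1 <= tc1 < tc2", call. = FALSE)
  }
  structure(list(tc1 = tc1, tc2 = tc2, other = other), class = "sync_events")
}

#' @export
print.sync_events <- function(x, ...) {
  cat(sprintf("<sync_events> tc1 = %d, tc2 = %d\n", x$tc1, x$tc2))
  invisible(x)
}
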