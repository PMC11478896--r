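#' Default CSV column schema for recordings
#'
#' Maps the canonical channel names used by the package to the column names
#' found in the CSV files. The CSV dialect is fixed: comma separated, `.`
#' decimal, header row required, time column in seconds.
#'
#' @param time,accel_norm,gyro_norm,fx,fy,mz Column names.
#' @return Named character vector (the schema).
#' @export
wk_schema <- function(time = "time", accel_norm = "accel_norm",
                      gyro_norm = "gyro_norm", fx = "fx", fy = "fy", mz = "mz") {
  c(time = time, accel_norm = accel_norm, gyro_norm = gyro_norm,
    fx = fx, fy = fy, mz = mz)
}

default_units <- c(accel_norm = "m/s^2", gyro_norm = "rad/s",
                   fx = "N", fy = "N", mz = "N.m")

# Infer a sampling rate from a monotone time-stamp column; errors when the
# sampling is non-uniform beyond `tol` (fraction of the nominal period).
infer_rate <- function(t, tol = 0.01, what = "channel") {
  if (length(t) < 2L) return(NA_real_)
  dt <- diff(t)
  if (any(dt <= 0)) {
    stop(sprintf("read_recording: non-monotone time stamps in %s", what),
         call. = FALSE)
  }
  period <- stats::median(dt)
  if (max(abs(dt - period)) > tol * period) {
    stop(sprintf(
      "read_recording: non-uniform sampling in %s (max deviation %.3g of the nominal period %.3g s)",
      what, max(abs(dt - period)) / period, period), call. = FALSE)
  }
  1 / period
}

read_channel_csv <- function(path, schema, channels, units, what) {
  df <- utils::read.csv(path, check.names = FALSE)
  tcol <- schema[["time"]]
  if (!tcol %in% names(df)) {
    stop(sprintf("read_recording: missing time column '%s' in %s", tcol, path),
         call. = FALSE)
  }
  rate <- infer_rate(df[[tcol]], what = what)
  out <- list()
  for (ch in channels) {
    col <- schema[[ch]]
    if (is.null(col) || !col %in% names(df)) {
      stop(sprintf("read_recording: missing column '%s' (%s) in %s",
                   col %||% ch, ch, path), call. = FALSE)
    }
    out[[ch]] <- time_series(df[[col]], rate = rate,
                             units = units[[ch]] %||% "",
                             t0 = df[[tcol]][1])
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a propulsion recording from CSV files
#'
#' A recording is stored as a pair of CSV files sharing a stem — IMU channels
#' in `<stem>_imu.csv` (time, acceleration norm, angular-velocity norm) and
#' kinetic channels in `<stem>_kin.csv` (time, Fx, Fy, Mz) — plus a JSON
#' sidecar `<stem>.json` holding side and units metadata. The kinetics file
#' is optional (deployment mode). Per-channel rates are inferred from the
#' time stamps; sampling must be uniform to within 1 % of the nominal period.
#'
#' @param stem Path stem (no extension).
#' @param schema Column map from [wk_schema()].
#' @return A [recording()].
#' @seealso [write_recording()]
#' @export
read_recording <- function(stem, schema = wk_schema()) {
  imu_path <- paste0(stem, "_imu.csv")
  kin_path <- paste0(stem, "_kin.csv")
  meta_path <- paste0(stem, ".json")
  if (!file.exists(imu_path)) {
    stop(sprintf("read_recording: no IMU file at %s", imu_path), call. = FALSE)
  }
  meta <- if (file.exists(meta_path)) {
    jsonlite::read_json(meta_path, simplifyVector = TRUE)
  } else list()
  units <- utils::modifyList(as.list(default_units), as.list(meta$units %||% list()))
  imu <- read_channel_csv(imu_path, schema, c("accel_norm", "gyro_norm"),
                          units, what = "IMU stream")
  kin <- if (file.exists(kin_path)) {
    read_channel_csv(kin_path, schema, c("fx", "fy", "mz"),
                     units, what = "kinetic stream")
  } else list(fx = NULL, fy = NULL, mz = NULL)
  recording(side = meta$side %||% "right",
            accel_norm = imu$accel_norm, gyro_norm = imu$gyro_norm,
            fx = kin$fx, fy = kin$fy, mz = kin$mz)
}

#' Write a propulsion recording to CSV files
#'
#' Inverse of [read_recording()]: writes `<stem>_imu.csv`, `<stem>_kin.csv`
#' (when kinetics are present) and the `<stem>.json` sidecar.
#'
#' @param rec A [recording()].
#' @param stem Path stem (no extension).
#' @param schema Column map from [wk_schema()].
#' @return Invisibly, the vector of files written.
#' @export
write_recording <- function(rec, stem, schema = wk_schema()) {
  stopifnot(inherits(rec, "wk_recording"))
  written <- character(0)
  imu <- data.frame(ts_time(rec$accel_norm), rec$accel_norm$values,
                    rec$gyro_norm$values)
  names(imu) <- schema[c("time", "accel_norm", "gyro_norm")]
  imu_path <- paste0(stem, "_imu.csv")
  utils::write.csv(imu, imu_path, row.names = FALSE)
  written <- c(written, imu_path)
  units <- list(accel_norm = rec$accel_norm$units, gyro_norm = rec$gyro_norm$units)
  if (has_kinetics(rec)) {
    kin <- data.frame(ts_time(rec$fx), rec$fx$values, rec$fy$values, rec$mz$values)
    names(kin) <- schema[c("time", "fx", "fy", "mz")]
    kin_path <- paste0(stem, "_kin.csv")
    utils::write.csv(kin, kin_path, row.names = FALSE)
    written <- c(written, kin_path)
    units <- c(units, list(fx = rec$fx$units, fy = rec$fy$units, mz = rec$mz$units))
  }
  meta_path <- paste0(stem, ".json")
  jsonlite::write_json(list(side = rec$side, units = units), meta_path,
                       auto_unbox = TRUE, digits = NA)
  invisible(c(written, meta_path))
}
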