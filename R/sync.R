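#' Detect the start/end kick synchronization events
#'
#' Trials are book-ended by the subject kicking the handrim, producing two
#' isolated high-amplitude transients visible in both the force and the
#' acceleration streams. Events are located on the absolute first difference
#' of each channel with a robust threshold (median + 6 MAD); super-threshold
#' local maxima are clustered, the event time is refined to the channel's
#' amplitude peak around each cluster, and the first and last clusters at
#' least `min_separation` seconds apart are returned. Temporal order decides
#' which event is which — not amplitude.
#'
#' @param primary A [time_series()] in which the events are reported
#'   (typically the force norm).
#' @param secondary Optional second `time_series` (typically the IMU
#'   acceleration norm); the same events are located in it independently and
#'   returned in `$other` so the two streams can be aligned.
#' @param mad_mult Threshold multiplier on the MAD of the derivative.
#' @param min_separation Minimum event separation in seconds.
#' @return A [sync_events()]; indices refer to `primary`.
#' @export
detect_sync_events <- function(primary, secondary = NULL, mad_mult = 6,
                               min_separation = 5) {
  ev <- locate_kicks(primary, mad_mult, min_separation)
  other <- if (!is.null(secondary)) locate_kicks(secondary, mad_mult, min_separation)
  sync_events(ev[1], ev[2], other = other)
}

locate_kicks <- function(ts, mad_mult, min_separation) {
  stopifnot(inherits(ts, "time_series"))
  x <- ts$values
  d <- abs(diff(x))
  thr <- stats::median(d) + mad_mult * stats::mad(d)
  hot <- which(d > thr)
  if (length(hot) == 0L) {
    stop(sprintf(
      "detect_sync_events: no transient above threshold %.4g (median + %g MAD of |diff|)",
      thr, mad_mult), call. = FALSE)
  }
  # cluster super-threshold samples closer than 1 s
  gap <- max(1L, round(ts$rate))
  brk <- c(0L, which(diff(hot) > gap), length(hot))
  clusters <- lapply(seq_len(length(brk) - 1L), function(i) {
    hot[(brk[i] + 1L):brk[i + 1L]]
  })
  centers <- vapply(clusters, function(cl) {
    # refine to the amplitude peak of the channel around the cluster
    lo <- max(1L, min(cl) - 10L); hi <- min(length(x), max(cl) + 10L)
    w <- lo:hi
    w[which.max(abs(x[w] - stats::median(x)))]
  }, numeric(1))
  centers <- sort(unique(centers))
  min_gap <- min_separation * ts$rate
  if (length(centers) < 2L || (centers[length(centers)] - centers[1]) < min_gap) {
    stop(sprintf(
      "detect_sync_events: fewer than two transients above threshold %.4g separated by >= %g s",
      thr, min_separation), call. = FALSE)
  }
  c(centers[1], centers[length(centers)])
}

#' Align the kinetic and IMU streams of a trial
#'
#' Downsamples the kinetic channels to the IMU rate, shifts the time axes so
#' the first kick events coincide, and corrects residual clock drift by a
#' linear time rescaling (a two-point clock model) so the second kick events
#' coincide as well. All channels are cropped to the overlap `[tc1, tc2]`.
#'
#' @param kinetics A [recording()] whose kinetic channels (Fx, Fy, Mz) are at
#'   the (higher) kinetic rate.
#' @param imu A [recording()] carrying the IMU channels, or the same
#'   recording when channels are bundled.
#' @param ev_kin [sync_events()] located in the kinetic stream.
#' @param ev_imu [sync_events()] located in the IMU stream.
#' @param tol Maximum fractional disagreement of the two event intervals.
#' @return An aligned [recording()] at the IMU rate; all channels span
#'   `tc2 - tc1 + 1` IMU samples starting at the first kick.
#' @export
align_streams <- function(kinetics, imu, ev_kin, ev_imu, tol = 0.05) {
  stopifnot(inherits(kinetics, "wk_recording"), inherits(imu, "wk_recording"),
            inherits(ev_kin, "sync_events"), inherits(ev_imu, "sync_events"))
  if (!has_kinetics(kinetics)) {
    stop("align_streams: kinetic channels absent", call. = FALSE)
  }
  kin_rate <- kinetics$mz$rate
  imu_rate <- imu$accel_norm$rate
  if (kin_rate < imu_rate) {
    stop("align_streams: kinetic rate must be >= IMU rate", call. = FALSE)
  }
  span_kin <- (ev_kin$tc2 - ev_kin$tc1) / kin_rate
  span_imu <- (ev_imu$tc2 - ev_imu$tc1) / imu_rate
  if (abs(span_kin - span_imu) > tol * span_imu) {
    stop(sprintf(
      "align_streams: event intervals disagree by %.2f%% (> %.0f%%): %.3f s vs %.3f s",
      100 * abs(span_kin - span_imu) / span_imu, 100 * tol, span_kin, span_imu),
      call. = FALSE)
  }
  n_out <- ev_imu$tc2 - ev_imu$tc1 + 1L
  t0 <- imu$accel_norm$t0 + (ev_imu$tc1 - 1L) / imu_rate
  # kinetics: rate conversion by polyphase, then linear time rescaling that
  # maps [tc1, tc2] (kinetic clock) onto the n_out IMU samples
  warp <- function(ch) {
    ds <- resample(ch$values, imu_rate / kin_rate)
    scale <- imu_rate / kin_rate
    k1 <- 1 + (ev_kin$tc1 - 1L) * scale
    k2 <- 1 + (ev_kin$tc2 - 1L) * scale
    pos <- seq(k1, k2, length.out = n_out)
    vals <- stats::approx(seq_along(ds), ds, xout = pos, rule = 2)$y
    time_series(vals, rate = imu_rate, units = ch$units, t0 = t0)
  }
  crop <- function(ch) {
    out <- ts_crop(ch, ev_imu$tc1, ev_imu$tc2)
    out$t0 <- t0
    out
  }
  recording(side = kinetics$side,
            accel_norm = crop(imu$accel_norm),
            gyro_norm = crop(imu$gyro_norm),
            fx = warp(kinetics$fx), fy = warp(kinetics$fy), mz = warp(kinetics$mz))
}
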