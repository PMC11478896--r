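#' Segment push cycles from the sagittal moment
#'
#' The sagittal moment Mz defines the push phase: each push is a maximal run
#' of samples where `Mz` exceeds a threshold relative to the trial-level Mz
#' RMS (default 10 %), with a short hysteresis (default 50 ms) that merges
#' brief dropouts and discards brief chatter. Each push phase `[start, end)`
#' (half-open) gets an extended analysis window adding 20 % of the push
#' duration on each side, so the window covers about 140 % of the push.
#' Cycles whose extended window leaves the record are dropped.
#'
#' @param mz A [time_series()] of the sagittal moment (aligned, steady-state
#'   portion between the sync events).
#' @param threshold_frac Onset/offset threshold as a fraction of the
#'   trial-level Mz RMS.
#' @param hysteresis Hysteresis duration in seconds.
#' @param extend Extension fraction added on each side of the push phase.
#' @return A `push_cycles` data frame with one row per cycle and integer
#'   columns `start`, `end`, `ext_start`, `ext_end` (all half-open
#'   `[start, end)` index pairs).
#' @export
segment_cycles <- function(mz, threshold_frac = 0.10, hysteresis = 0.050,
                           extend = 0.20) {
  stopifnot(inherits(mz, "time_series"))
  x <- mz$values
  n <- length(x)
  thr <- threshold_frac * sqrt(mean(x^2))
  if (!is.finite(thr) || thr <= 0) {
    stop("segment_cycles: degenerate moment channel (zero RMS)", call. = FALSE)
  }
  above <- x > thr
  if (!any(above)) {
    stop(sprintf("segment_cycles: no push cycle found (threshold %.4g)", thr),
         call. = FALSE)
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hyst <- max(1L, round(hysteresis * mz$rate))
  # merge active runs separated by sub-hysteresis gaps
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  if (nrow(runs) > 1L) {
    merged <- runs[1, , drop = FALSE]
    for (i in 2:nrow(runs)) {
      if (runs$start[i] - merged$end[nrow(merged)] - 1L < hyst) {
        merged$end[nrow(merged)] <- runs$end[i]
      } else {
        merged <- rbind(merged, runs[i, ])
      }
    }
    runs <- merged
  }
  # discard chatter shorter than the hysteresis
  runs <- runs[runs$end - runs$start + 1L >= hyst, , drop = FALSE]
  if (nrow(runs) == 0L) {
    stop("segment_cycles: no push cycle survives the hysteresis", call. = FALSE)
  }
  # half-open [start, end); extended window adds extend * duration per side
  start <- runs$start
  end <- runs$end + 1L
  dur <- end - start
  e <- round(extend * dur)
  cyc <- data.frame(start = start, end = end,
                    ext_start = start - e, ext_end = end + e)
  keep <- cyc$ext_start >= 1L & cyc$ext_end <= n + 1L
  cyc <- cyc[keep, , drop = FALSE]
  if (nrow(cyc) == 0L) {
    stop("segment_cycles: all cycles lose their extended window at the record edges",
         call. = FALSE)
  }
  rownames(cyc) <- NULL
  structure(cyc, class = c("push_cycles", "data.frame"), rate = mz$rate)
}

#' RMS-normalize a channel over one push cycle
#'
#' Divides the channel on the cycle's extended window by the root mean
#' square computed over the push phase (the default, making the normalized
#' push-phase RMS exactly 1) or over the whole extended window. The stored
#' factor allows exact de-normalization.
#'
#' @param cycle One row of a [segment_cycles()] result (or any list with
#'   `start`, `end`, `ext_start`, `ext_end`).
#' @param channel A [time_series()] or numeric vector covering the cycle.
#' @param window Window over which the RMS factor is computed: the push
#'   phase (`"push"`, default) or the 140 % extended window (`"extended"`).
#' @return A list with `values` (normalized samples over the extended
#'   window) and `factor` (the RMS, in channel units).
#' @export
rms_normalize <- function(cycle, channel, window = c("push", "extended")) {
  window <- match.arg(window)
  x <- if (inherits(channel, "time_series")) channel$values else as.numeric(channel)
  idx <- if (window == "push") cycle$start:(cycle$end - 1L)
         else cycle$ext_start:(cycle$ext_end - 1L)
  rms <- sqrt(mean(x[idx]^2))
  if (!is.finite(rms) || rms <= 0) {
    stop("rms_normalize: zero RMS over the cycle (degenerate cycle)",
         call. = FALSE)
  }
  list(values = x[cycle$ext_start:(cycle$ext_end - 1L)] / rms, factor = rms)
}

cycle_list <- function(cycles) {
  lapply(seq_len(nrow(cycles)), function(i) as.list(cycles[i, ]))
}

#' Per-subject generic pattern of a normalized channel
#'
#' Each cycle's RMS-normalized extended-window sequence is time-rescaled to a
#' fixed length `L` (linear interpolation on the normalized 0-140 % time
#' base) and averaged pointwise across cycles. The result is the subject's
#' generic force/moment pattern, used as the third input of the
#' Hammerstein-Wiener model.
#'
#' @param cycles A [segment_cycles()] result.
#' @param channel A [time_series()] or numeric vector covering all cycles.
#' @param L Pattern length in samples (default 140: one point per percent of
#'   the push cycle).
#' @param window RMS window passed to [rms_normalize()].
#' @return An object of class `generic_pattern` with fields `values`
#'   (length `L`) and `L`.
#' @export
compute_generic_pattern <- function(cycles, channel, L = 140L,
                                    window = c("push", "extended")) {
  window <- match.arg(window)
  if (is.null(cycles) || nrow(cycles) == 0L) {
    stop("compute_generic_pattern: need at least one cycle", call. = FALSE)
  }
  acc <- matrix(0, nrow = nrow(cycles), ncol = L)
  for (i in seq_len(nrow(cycles))) {
    cyc <- as.list(cycles[i, ])
    nv <- rms_normalize(cyc, channel, window)$values
    acc[i, ] <- rescale_to(nv, L)
  }
  structure(list(values = colMeans(acc), L = as.integer(L)),
            class = "generic_pattern")
}

# linear time-rescaling of a sequence to length L on a shared [0, 1] base
rescale_to <- function(x, L) {
  n <- length(x)
  if (n == L) return(x)
  stats::approx(seq(0, 1, length.out = n), x, xout = seq(0, 1, length.out = L))$y
}

#' Lay the generic pattern out as a continuous input channel
#'
#' Builds the third Hammerstein-Wiener input: the generic pattern is
#' rescaled to each cycle's extended duration and placed at the cycle's
#' extended window. Where adjacent extended windows overlap the two copies
#' are averaged; gaps between windows are filled with the mean of the
#' pattern's two boundary values.
#'
#' @param pattern A [compute_generic_pattern()] result.
#' @param cycles A [segment_cycles()] result.
#' @param n Total length of the output channel (defaults to the last
#'   extended window's end).
#' @param rate Sampling rate attached to the output (Hz).
#' @return A dimensionless [time_series()] of length `n`.
#' @export
pattern_as_input <- function(pattern, cycles, n = max(cycles$ext_end) - 1L,
                             rate = attr(cycles, "rate") %||% 1) {
  stopifnot(inherits(pattern, "generic_pattern"))
  fill <- mean(pattern$values[c(1L, pattern$L)])
  acc <- numeric(n)
  cnt <- numeric(n)
  for (i in seq_len(nrow(cycles))) {
    a <- cycles$ext_start[i]; b <- cycles$ext_end[i] - 1L
    if (a < 1L || b > n) next
    copy <- rescale_to(pattern$values, b - a + 1L)
    acc[a:b] <- acc[a:b] + copy
    cnt[a:b] <- cnt[a:b] + 1
  }
  vals <- ifelse(cnt > 0, acc / pmax(cnt, 1), fill)
  time_series(vals, rate = rate, units = "")
}

#' Per-cycle RMS factors for a set of channels
#'
#' Convenience wrapper: computes the [rms_normalize()] factor of every cycle
#' for each named channel, as used for the cycle tables exported to CSV.
#'
#' @param cycles A [segment_cycles()] result.
#' @param channels Named list of [time_series()] / numeric vectors.
#' @param window RMS window passed to [rms_normalize()].
#' @return `cycles` with one extra `rms_<name>` column per channel.
#' @export
cycle_rms_table <- function(cycles, channels, window = c("push", "extended")) {
  window <- match.arg(window)
  out <- as.data.frame(cycles)
  for (nm in names(channels)) {
    out[[paste0("rms_", nm)]] <- vapply(
      cycle_list(cycles),
      function(cyc) rms_normalize(cyc, channels[[nm]], window)$factor,
      numeric(1))
  }
  out
}
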