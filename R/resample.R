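#' Rational-ratio polyphase resampling
#'
#' Resamples a channel to a new rate by the classic polyphase scheme:
#' zero-stuff by `p`, low-pass with a windowed-sinc FIR kernel
#' ([signal::fir1()]) at the tighter of the two Nyquist limits, then take
#' every `q`-th sample. The FIR group delay is compensated exactly (the
#' kernel has an even order, hence an integer delay on the upsampled grid)
#' and edges are padded by odd reflection so constants and slow trends pass
#' through unchanged. The anti-alias kernel is intrinsic to rational-ratio
#' resampling; no additional smoothing is applied on top of it.
#'
#' @param ts A [time_series()] (or plain numeric vector).
#' @param target_rate Desired rate in Hz (> 0). Ignored when `p`/`q` given.
#' @param p,q Optional explicit up/down factors overriding the rational
#'   approximation of `target_rate / rate`.
#' @param taps_per_phase Half-width of the FIR kernel per polyphase branch
#'   (kernel order is `2 * taps_per_phase * max(p, q)`).
#' @return For a `time_series` input, a `time_series` at the new rate with
#'   length `round(n * target_rate / rate)` and unchanged units; for a
#'   numeric input, a numeric vector.
#' @examples
#' x <- time_series(sin(2 * pi * 5 * (0:479) / 240), rate = 240)
#' y <- resample(x, 120)
#' length(y$values)  # 240
#' @export
resample <- function(ts, target_rate, p = NULL, q = NULL, taps_per_phase = 10L) {
  if (inherits(ts, "time_series")) {
    vals <- resample_core(ts$values, target_rate / ts$rate, p, q, taps_per_phase)
    return(time_series(vals, rate = if (is.null(p)) target_rate else ts$rate * p / q,
                       units = ts$units, t0 = ts$t0))
  }
  resample_core(as.numeric(ts), target_rate, p, q, taps_per_phase)
}

# ratio as a reduced fraction p/q with bounded denominator (continued fractions)
rational_ratio <- function(r, max_den = 1000L, tol = 1e-9) {
  stopifnot(is.finite(r), r > 0)
  p0 <- 0L; q0 <- 1L; p1 <- 1L; q1 <- 0L
  x <- r
  for (i in 1:64) {
    a <- floor(x)
    p2 <- a * p1 + p0; q2 <- a * q1 + q0
    if (q2 > max_den) break
    p0 <- p1; q0 <- q1; p1 <- p2; q1 <- q2
    if (abs(p1 / q1 - r) < tol * r) break
    frac <- x - a
    if (frac < 1e-12) break
    x <- 1 / frac
  }
  c(p = as.integer(p1), q = as.integer(q1))
}

resample_core <- function(x, ratio, p = NULL, q = NULL, taps_per_phase = 10L) {
  if (is.null(p) || is.null(q)) {
    if (!is.numeric(ratio) || length(ratio) != 1L || !is.finite(ratio) || ratio <= 0) {
      stop("resample: target rate must be a positive scalar", call. = FALSE)
    }
    pq <- rational_ratio(ratio)
    p <- pq[["p"]]; q <- pq[["q"]]
  }
  n <- length(x)
  n_out <- round(n * p / q)
  if (p == q) return(x)
  if (n < 4L) {  # too short for a kernel: linear interpolation
    if (n == 1L) return(rep(x, max(n_out, 1L)))
    return(stats::approx(seq_len(n), x, xout = 1 + (seq_len(n_out) - 1L) * q / p,
                         rule = 2)$y)
  }
  m <- max(p, q)
  half <- taps_per_phase * m          # kernel half-width on the upsampled grid
  # odd reflection about the first/last samples preserves level and slope
  npad <- ceiling(half / p) + 2L
  npad <- min(npad, n - 1L)
  left <- 2 * x[1] - x[seq(npad + 1L, 2L, by = -1L)]
  right <- 2 * x[n] - x[seq(n - 1L, n - npad, by = -1L)]
  xp <- c(left, x, right)
  # upsample: zero-stuff by p
  up <- numeric(length(xp) * p)
  up[seq(1L, length(up), by = p)] <- xp
  # anti-alias / interpolation kernel: cutoff at the tighter Nyquist, gain p;
  # each polyphase branch is normalized to unit sum so constants pass exactly
  kern <- p * signal::fir1(2L * half, 1 / m)
  for (j in seq_len(p)) {
    idx <- seq(j, length(kern), by = p)
    kern[idx] <- kern[idx] / sum(kern[idx])
  }
  y_up <- stats::convolve(up, rev(kern), type = "open")
  # sample k of x sits at index npad*p + (k-1)*p + 1 + half after convolution
  out_idx <- npad * p + half + 1L + (seq_len(n_out) - 1L) * q
  y_up[out_idx]
}
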