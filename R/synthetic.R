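#' Parameters of the synthetic propulsion generator
#'
#' Defaults emulate steady-state straight-line propulsion at self-selected
#' speed: 30-38 quasi-periodic cycles at about 1 Hz cadence with a push
#' phase occupying ~35 % of the cycle, wrist acceleration-norm statistics of
#' 7.89 (SD 5.12, max 52.13) m/s^2, angular-velocity statistics of 2.98
#' (SD 1.18, max 9.75) rad/s, horizontal force peaks around 60 N, and kick
#' synchronization transients bracketing the trial. Kinetics are emitted at
#' 240 Hz and IMU channels at 120 Hz with a configurable clock offset/drift
#' between the two streams.
#'
#' @param n_cycles Number of push cycles (30-38 is the realistic range).
#' @param cadence Mean cycle rate in Hz.
#' @param duty Push-phase fraction of the cycle, in (0, 1).
#' @param accel_mean,accel_sd,accel_max Wrist acceleration-norm targets
#'   (m/s^2) over the steady propulsion region.
#' @param gyro_mean,gyro_sd,gyro_max Angular-velocity-norm targets (rad/s).
#' @param fx_peak,fy_peak,mz_peak Mean per-cycle kinetic peak amplitudes
#'   (N, N, N.m).
#' @param noise_sd Named list of additive Gaussian noise SDs per channel.
#' @param imu_rate,kin_rate Sampling rates (Hz).
#' @param clock_offset IMU clock offset relative to the kinetic clock (s).
#' @param clock_drift Fractional IMU clock-rate error (e.g. `0.005` = 0.5 %).
#' @param amp_jitter Lognormal sigma of per-cycle amplitude jitter.
#' @param dur_jitter Lognormal sigma of per-cycle duration jitter.
#' @param rise_frac Rise fraction of the asymmetric raised half-sine pulse.
#' @param kin_lowpass Apply the measurement-chain 2nd-order 30 Hz Butterworth
#'   low-pass to the kinetic channels (off by default so block-oracle tests
#'   see the exact waveform).
#' @param seed RNG seed; the generator is bitwise-deterministic per seed.
#' @return A list of class `gen_params`.
#' @export
gen_params <- function(n_cycles = 34L, cadence = 1, duty = 0.35,
                       accel_mean = 7.89, accel_sd = 5.12, accel_max = 52.13,
                       gyro_mean = 2.98, gyro_sd = 1.18, gyro_max = 9.75,
                       fx_peak = 60, fy_peak = 50, mz_peak = 12,
                       noise_sd = list(accel = 0.3, gyro = 0.1,
                                       fx = 0.5, fy = 0.5, mz = 0.05),
                       imu_rate = 120, kin_rate = 240,
                       clock_offset = 0, clock_drift = 0,
                       amp_jitter = 0.2, dur_jitter = 0.05, rise_frac = 0.4,
                       kin_lowpass = FALSE, seed = 1L) {
  p <- as.list(environment())
  with(p, {
    stopifnot(n_cycles >= 1L, cadence > 0, duty > 0, duty < 1,
              imu_rate > 0, kin_rate >= imu_rate)
    if (accel_max < accel_mean || gyro_max < gyro_mean) {
      stop("gen_params: channel max target below its mean target", call. = FALSE)
    }
  })
  structure(p, class = "gen_params")
}

# asymmetric raised half-sine: tau in [0,1], rises over rise_frac of support
pulse_shape <- function(tau, rise_frac) {
  w <- ifelse(tau < rise_frac, tau / (2 * rise_frac),
              0.5 + (tau - rise_frac) / (2 * (1 - rise_frac)))
  out <- sin(pi * pmin(pmax(w, 0), 1))
  out[tau < 0 | tau >= 1] <- 0
  out
}

# narrow triangular transient centred at t0 with half-width hw
spike_shape <- function(t, t0, hw) pmax(0, 1 - abs(t - t0) / hw)

#' Generate a synthetic propulsion recording
#'
#' Emits a bilateral-style single-side recording with quasi-periodic push
#' pulses (per-cycle lognormal amplitude and duration jitter), a narrow
#' hand-contact transient at each push onset on the acceleration channel,
#' kick synchronization spikes 2 s before the first and after the last
#' cycle, additive Gaussian noise, and nonnegative IMU norms. The smooth
#' waveform is calibrated per realization so the noise-free steady-region
#' mean and SD of the IMU channels match the targets exactly and the
#' noise-free maximum matches the max target.
#'
#' @param p A [gen_params()].
#' @return List with `recording` (a [recording()]; IMU at `imu_rate`,
#'   kinetics at `kin_rate`) and `truth`, the ground truth: cycle start/end
#'   times and indices on both sample grids, kick times/indices, per-cycle
#'   kinetic peaks, and the parameters.
#' @export
generate_recording <- function(p = gen_params()) {
  stopifnot(inherits(p, "gen_params"))
  set.seed(p$seed)
  nc <- p$n_cycles
  # per-cycle realizations (mean-corrected lognormal jitter)
  amp <- exp(stats::rnorm(nc, 0, p$amp_jitter) - p$amp_jitter^2 / 2)
  amp_k <- exp(stats::rnorm(nc, 0, p$amp_jitter) - p$amp_jitter^2 / 2)
  period <- exp(stats::rnorm(nc, 0, p$dur_jitter)) / p$cadence
  lead <- 4                                  # 2 s to kick + 2 s after it
  push_start <- lead + cumsum(c(0, period[-nc]))
  push_dur <- p$duty * period
  push_end <- push_start + push_dur
  t_end <- push_end[nc] + lead
  kick_t <- c(push_start[1] - 2, push_end[nc] + 2)
  kick_hw <- 1.5 / p$kin_rate                # 3-sample transient at 240 Hz

  smooth_of <- function(t, amps, rise) {
    out <- numeric(length(t))
    for (k in seq_len(nc)) {
      tau <- (t - push_start[k]) / push_dur[k]
      idx <- which(tau >= 0 & tau < 1)
      if (length(idx)) out[idx] <- out[idx] + amps[k] * pulse_shape(tau[idx], rise)
    }
    out
  }
  contact_of <- function(t) {   # hand-contact transient at each push onset
    out <- numeric(length(t))
    for (k in seq_len(nc)) {
      out <- out + amp[k] * spike_shape(t, push_start[k] + 0.3 * push_dur[k], 0.02)
    }
    out
  }
  kicks_of <- function(t, height) {
    height * (spike_shape(t, kick_t[1], kick_hw) + spike_shape(t, kick_t[2], kick_hw))
  }

  # IMU clock: offset + fractional rate error relative to the kinetic clock
  n_imu <- floor(t_end * p$imu_rate)
  t_imu <- p$clock_offset + (seq_len(n_imu) - 1) / (p$imu_rate * (1 + p$clock_drift))
  n_kin <- floor(t_end * p$kin_rate)
  t_kin <- (seq_len(n_kin) - 1) / p$kin_rate

  steady <- t_imu >= push_start[1] & t_imu < push_end[nc]
  calibrate <- function(tgt_mean, tgt_sd, tgt_max, noise, spike_unit = NULL) {
    base_unit <- smooth_of(t_imu, amp, p$rise_frac)
    sd_eff <- sqrt(max(tgt_sd^2 - noise^2, (0.1 * tgt_sd)^2))
    stats_for <- function(h) {
      u <- base_unit + if (is.null(spike_unit)) 0 else h * spike_unit
      us <- u[steady]
      s <- sd_eff / stats::sd(us)
      b <- tgt_mean - s * mean(us)
      list(u = u, s = s, b = b, mx = b + s * max(us))
    }
    if (is.null(spike_unit)) {
      st <- stats_for(0)
    } else {
      f <- function(h) stats_for(h)$mx - tgt_max
      if (f(0) >= 0) {
        h <- 0
      } else {
        hi <- 1
        while (f(hi) < 0 && hi < 64) hi <- hi * 2
        # max is a soft target: without amplitude jitter the peak-to-SD ratio
        # of the waveform is bounded and the best achievable height is kept
        h <- if (f(hi) < 0) hi else stats::uniroot(f, c(0, hi))$root
      }
      st <- stats_for(h)
    }
    pmax(0, st$b + st$s * st$u)
  }

  accel <- calibrate(p$accel_mean, p$accel_sd, p$accel_max, p$noise_sd$accel,
                     spike_unit = contact_of(t_imu))
  gyro <- calibrate(p$gyro_mean, p$gyro_sd, p$gyro_max, p$noise_sd$gyro,
                    spike_unit = contact_of(t_imu))
  accel <- accel + kicks_of(t_imu, 8 * max(accel))
  accel <- pmax(0, accel + stats::rnorm(n_imu, 0, p$noise_sd$accel))
  gyro <- pmax(0, gyro + stats::rnorm(n_imu, 0, p$noise_sd$gyro))

  kin_of <- function(peak, noise) {
    x <- smooth_of(t_kin, peak * amp_k, p$rise_frac) + kicks_of(t_kin, 8 * peak)
    if (p$kin_lowpass) {
      bw <- signal::butter(2, 30 / (p$kin_rate / 2))
      x <- as.numeric(signal::filter(bw, x))
    }
    x + stats::rnorm(n_kin, 0, noise)
  }
  fx <- kin_of(p$fx_peak, p$noise_sd$fx)
  fy <- kin_of(p$fy_peak, p$noise_sd$fy)
  mz <- kin_of(p$mz_peak, p$noise_sd$mz)

  rec <- recording(
    side = "right",
    accel_norm = time_series(accel, p$imu_rate, "m/s^2"),
    gyro_norm = time_series(gyro, p$imu_rate, "rad/s"),
    fx = time_series(fx, p$kin_rate, "N"),
    fy = time_series(fy, p$kin_rate, "N"),
    mz = time_series(mz, p$kin_rate, "N.m"))

  to_idx <- function(tt, grid_t) {
    vapply(tt, function(ti) which.min(abs(grid_t - ti)), integer(1))
  }
  truth <- list(
    cycles = data.frame(
      start_time = push_start, end_time = push_end,
      start_imu = to_idx(push_start, t_imu), end_imu = to_idx(push_end, t_imu),
      start_kin = to_idx(push_start, t_kin), end_kin = to_idx(push_end, t_kin),
      peak_fx = p$fx_peak * amp_k, peak_fy = p$fy_peak * amp_k,
      peak_mz = p$mz_peak * amp_k),
    kick_time = kick_t,
    kick_imu = to_idx(kick_t, t_imu), kick_kin = to_idx(kick_t, t_kin),
    params = p)
  list(recording = rec, truth = truth)
}

#' Generate a recording whose kinetics come from a known HW model
#'
#' Recovery-test harness: IMU channels are generated as in
#' [generate_recording()]; the kinetic target is produced by simulating the
#' given Hammerstein-Wiener model on the per-cycle RMS-normalized inputs
#' (plus the generic-pattern third input computed from the baseline
#' kinetics), de-normalized by the baseline per-cycle RMS factors, and
#' emitted at the kinetic rate with optional Gaussian noise. The exact
#' normalized dataset used for simulation is returned in the ground truth so
#' identification experiments can run free of resampling round-trip error.
#'
#' @param model An [hw_model()] (stable or marginally stable).
#' @param p A [gen_params()]; `noise_sd` of the target channel applies to
#'   the normalized target in the ground-truth dataset as well.
#' @return As [generate_recording()], with `truth$hw_model` and
#'   `truth$dataset` (an `hw_dataset` of simulated normalized cycles) added.
#' @export
generate_from_hw <- function(model, p = gen_params()) {
  stopifnot(inherits(model, "hw_model"))
  base <- generate_recording(p)
  rec <- base$recording
  channel <- model$channel
  n_imu <- length(rec$accel_norm$values)
  down <- function(ch) {
    out <- resample(ch, p$imu_rate)
    if (length(out$values) > n_imu) out <- ts_crop(out, 1L, n_imu)
    out
  }
  aligned <- recording(
    side = rec$side,
    accel_norm = rec$accel_norm, gyro_norm = rec$gyro_norm,
    fx = down(rec$fx), fy = down(rec$fy), mz = down(rec$mz))
  # segment the steady region between the kicks (1 s margin inside each)
  margin <- round(p$imu_rate)
  lo <- base$truth$kick_imu[1] + margin
  hi <- min(base$truth$kick_imu[2] - margin, n_imu)
  cycles <- segment_cycles(ts_crop(aligned$mz, lo, hi))
  for (col in c("start", "end", "ext_start", "ext_end")) {
    cycles[[col]] <- cycles[[col]] + lo - 1L
  }
  pattern <- compute_generic_pattern(cycles, aligned[[channel]])
  data <- hw_make_dataset(aligned, cycles, pattern, channel)
  noise <- p$noise_sd[[if (channel == "mz") "mz" else channel]] /
    mean(vapply(data, function(cyc) cyc$factor, numeric(1)))
  sim <- lapply(data, function(cyc) {
    y <- hw_simulate(model, cyc$inputs)
    if (!all(is.finite(y))) {
      worst <- which.max(vapply(model$linear,
                                function(b) max(c(0, Mod(lb_poles(b)))), numeric(1)))
      stop(sprintf(
        "generate_from_hw: simulation diverged; largest pole |z| = %.4f in block %d",
        max(Mod(lb_poles(model$linear[[worst]]))), worst), call. = FALSE)
    }
    cyc$target <- y + stats::rnorm(length(y), 0, noise)
    cyc
  })
  sim <- structure(sim, class = "hw_dataset", channel = channel)
  # de-normalize and place into a continuous channel at the IMU rate
  chan <- numeric(length(aligned$mz$values))
  cnt <- numeric(length(chan))
  for (i in seq_along(sim)) {
    cyc <- sim[[i]]$cycle
    idx <- cyc$ext_start:(cyc$ext_end - 1L)
    chan[idx] <- chan[idx] + sim[[i]]$target * sim[[i]]$factor
    cnt[idx] <- cnt[idx] + 1
  }
  chan <- ifelse(cnt > 0, chan / pmax(cnt, 1), 0)
  out_kin <- resample(time_series(chan, p$imu_rate,
                                  units = rec[[channel]]$units), p$kin_rate)
  rec[[channel]] <- out_kin
  truth <- base$truth
  truth$hw_model <- model
  truth$dataset <- sim
  truth$cycles_imu <- cycles
  list(recording = rec, truth = truth)
}
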