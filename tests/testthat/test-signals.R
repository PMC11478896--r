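# time-series container, CSV I/O, kick detection, resampling, alignment

test_that("recording CSV round trip preserves values and infers rates", {
  stem <- file.path(tempdir(), "rt")
  imu_t <- (0:359) / 120
  kin_t <- (0:719) / 240
  rec <- recording(
    side = "left",
    accel_norm = time_series(5 + sin(imu_t), 120, "m/s^2"),
    gyro_norm = time_series(2 + cos(imu_t), 120, "rad/s"),
    fx = time_series(sin(2 * pi * kin_t), 240, "N"),
    fy = time_series(cos(2 * pi * kin_t), 240, "N"),
    mz = time_series(abs(sin(pi * kin_t)), 240, "N.m"))
  write_recording(rec, stem)
  back <- read_recording(stem)
  expect_equal(back$side, "left")
  expect_equal(back$accel_norm$rate, 120, tolerance = 1e-9)
  expect_equal(back$mz$rate, 240, tolerance = 1e-9)
  expect_equal(back$accel_norm$values, rec$accel_norm$values, tolerance = 1e-9)
  expect_equal(back$mz$values, rec$mz$values, tolerance = 1e-9)
  expect_equal(back$fx$units, "N")
})

test_that("read_recording rejects missing columns and non-uniform sampling", {
  stem <- file.path(tempdir(), "bad")
  utils::write.csv(data.frame(time = (0:2) / 120, accel_norm = 1:3),
                   paste0(stem, "_imu.csv"), row.names = FALSE)
  expect_error(read_recording(stem), "missing column 'gyro_norm'")
  utils::write.csv(data.frame(time = c(0, 1 / 120, 3 / 120),
                              accel_norm = 1:3, gyro_norm = 1:3),
                   paste0(stem, "_imu.csv"), row.names = FALSE)
  expect_error(read_recording(stem), "non-uniform sampling")
})

test_that("three-row CSV reads as a length-3 channel at 120 Hz", {
  stem <- file.path(tempdir(), "tiny")
  utils::write.csv(data.frame(time = (0:2) / 120, accel_norm = 1:3,
                              gyro_norm = c(0.1, 0.2, 0.3)),
                   paste0(stem, "_imu.csv"), row.names = FALSE)
  rec <- read_recording(stem)
  expect_length(rec$accel_norm$values, 3)
  expect_equal(rec$accel_norm$rate, 120, tolerance = 1e-6)
  expect_null(rec$mz)
  expect_false(has_kinetics(rec))
})

test_that("kick events are found at the right samples in temporal order", {
  base <- sin(2 * pi * 2 * (0:999) / 100)            # steady band, amplitude 1
  x <- base
  x[50] <- 10; x[950] <- 10
  ev <- detect_sync_events(time_series(x, 100))
  expect_equal(c(ev$tc1, ev$tc2), c(50, 950))

  # prominence order must not matter, only temporal order
  x2 <- base
  x2[50] <- 8; x2[950] <- 12
  ev2 <- detect_sync_events(time_series(x2, 100))
  expect_equal(c(ev2$tc1, ev2$tc2), c(50, 950))
  x3 <- base
  x3[50] <- 12; x3[950] <- 8
  ev3 <- detect_sync_events(time_series(x3, 100))
  expect_equal(c(ev3$tc1, ev3$tc2), c(50, 950))

  expect_error(detect_sync_events(time_series(base, 100)), "transient")
})

test_that("generator kick events are recovered within 2 samples", {
  g <- generate_recording(gen_params(seed = 11))
  ev_imu <- detect_sync_events(g$recording$accel_norm)
  ev_kin <- detect_sync_events(
    time_series(sqrt(g$recording$fx$values^2 + g$recording$fy$values^2), 240))
  expect_near(c(ev_imu$tc1, ev_imu$tc2), g$truth$kick_imu, 2.5)
  expect_near(c(ev_kin$tc1, ev_kin$tc2), g$truth$kick_kin, 2.5)
})

test_that("resampling preserves constants, slow sines and linearity", {
  const <- time_series(rep(3.7, 480), 240, "N")
  down <- resample(const, 120)
  expect_length(down$values, 240)
  expect_equal(down$rate, 120)
  expect_near(down$values, 3.7, 1e-9)

  s <- time_series(sin(2 * pi * 5 * (0:479) / 240), 240)
  ds <- resample(s, 120)
  ref <- sin(2 * pi * 5 * seq(0, by = 1 / 120, length.out = length(ds$values)))
  expect_near(ds$values, ref, 0.01)          # 5 Hz is far below Nyquist

  same <- resample(s, 240)
  expect_equal(same$values, s$values, tolerance = 1e-12)

  set.seed(3)
  a <- rnorm(480); b <- rnorm(480)
  lhs <- resample(2 * a + 3 * b, 0.5)
  rhs <- 2 * resample(a, 0.5) + 3 * resample(b, 0.5)
  expect_near(lhs, rhs, 1e-9)

  expect_error(resample(s, -1), "positive")
})

test_that("alignment removes a pure delay exactly", {
  rate_i <- 120; rate_k <- 240
  t_i <- (0:1499) / rate_i
  sig <- function(t) 2 + sin(2 * pi * 0.9 * t)
  imu <- recording("right",
                   accel_norm = time_series(sig(t_i), rate_i, "m/s^2"),
                   gyro_norm = time_series(sig(t_i), rate_i, "rad/s"))
  delay <- 1.0                                # kinetics start 1 s late
  t_k <- (0:2999) / rate_k - delay
  kin <- recording("right",
                   accel_norm = time_series(rep(1, 10), rate_i),
                   gyro_norm = time_series(rep(1, 10), rate_i),
                   fx = time_series(sig(t_k), rate_k, "N"),
                   fy = time_series(sig(t_k), rate_k, "N"),
                   mz = time_series(sig(t_k), rate_k, "N.m"))
  # events at matching physical times 2 s and 10 s
  ev_imu <- sync_events(2 * rate_i + 1, 10 * rate_i + 1)
  ev_kin <- sync_events((2 + delay) * rate_k + 1, (10 + delay) * rate_k + 1)
  al <- align_streams(kin, imu, ev_kin, ev_imu)
  expect_length(al$mz$values, 8 * rate_i + 1)
  expect_near(al$mz$values, al$accel_norm$values, 0.01)
})

test_that("alignment is the identity on already-aligned recordings", {
  t_i <- (0:1199) / 120
  sig <- 3 + sin(2 * pi * t_i)
  rec <- recording("right",
                   accel_norm = time_series(sig, 120, "m/s^2"),
                   gyro_norm = time_series(sig, 120, "rad/s"),
                   fx = time_series(sig, 120, "N"),
                   fy = time_series(sig, 120, "N"),
                   mz = time_series(sig, 120, "N.m"))
  ev <- sync_events(101, 1101)
  al <- align_streams(rec, rec, ev, ev)
  expect_near(al$mz$values, sig[101:1101], 1e-6)
  al2 <- align_streams(al, al, sync_events(1, length(al$mz$values)),
                       sync_events(1, length(al$mz$values)))
  expect_near(al2$mz$values, al$mz$values, 1e-9)
})

test_that("0.5 % clock drift is corrected to within one sample", {
  g <- generate_recording(gen_params(seed = 5, clock_drift = 0.005))
  rec <- g$recording
  ev_imu <- detect_sync_events(rec$accel_norm)
  ev_kin <- detect_sync_events(
    time_series(sqrt(rec$fx$values^2 + rec$fy$values^2), 240))
  al <- align_streams(rec, rec, ev_kin, ev_imu)
  # after alignment the kick transients must land on the window edges
  n <- length(al$mz$values)
  edge_pk <- which.max(abs(al$fx$values[1:30]))
  end_pk <- n - 30 + which.max(abs(al$fx$values[(n - 29):n]))
  expect_lte(edge_pk - 1, 1)
  expect_lte(n - end_pk, 1)
  expect_error(align_streams(rec, rec, sync_events(1, 10000), ev_imu),
               "disagree")
})
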