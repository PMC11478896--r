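# error metrics, peaks, Bland-Altman agreement, peak ANOVA, report tables

test_that("RMSE and MAE follow their closed forms", {
  x <- rnorm(50)
  expect_equal(unname(error_metrics(x, x)), c(0, 0))
  e <- error_metrics(x, x - 0.7)
  expect_equal(unname(e), c(0.7, 0.7), tolerance = 1e-12)
  m <- c(1, -1, 3, -3); p <- numeric(4)
  e2 <- error_metrics(m, p)
  expect_equal(unname(e2["rmse"]), sqrt(5), tolerance = 1e-12)
  expect_equal(unname(e2["mae"]), 2, tolerance = 1e-12)
  # de-normalization scales both metrics
  e3 <- error_metrics(m, p, denorm_factor = 10)
  expect_equal(unname(e3), 10 * unname(e2), tolerance = 1e-12)
  expect_error(error_metrics(1:3, 1:4), "length")
  expect_error(error_metrics(1:3, 1:3, denorm_factor = 0), "> 0")
})

test_that("MAE never exceeds RMSE", {
  set.seed(50)
  for (rep in 1:25) {
    m <- rnorm(100); p <- rnorm(100)
    e <- error_metrics(m, p, denorm_factor = runif(1, 0.1, 10))
    expect_lte(e["mae"], e["rmse"] + 1e-12)
  }
})

test_that("push-phase peaks are extracted from the right window", {
  A <- 4.4; L <- 60
  chan <- c(numeric(30), A * sin(pi * (0:(L - 1)) / L), numeric(30))
  cyc <- list(start = 31L, end = 91L, ext_start = 19L, ext_end = 103L)
  expect_equal(peak_extract(cyc, chan), A, tolerance = 1e-6)
  ramp <- seq_len(120)
  expect_equal(peak_extract(cyc, ramp), 90)   # half-open: end - 1
  expect_error(peak_extract(list(start = 5L, end = 5L), chan), "empty")
  # generator ground truth: recorded peaks match the emitted channel
  p <- gen_params(seed = 51, n_cycles = 10,
                  noise_sd = list(accel = 0, gyro = 0, fx = 0, fy = 0, mz = 0))
  g <- generate_recording(p)
  gt <- g$truth
  for (i in seq_len(nrow(gt$cycles))) {
    cyc <- list(start = gt$cycles$start_kin[i], end = gt$cycles$end_kin[i])
    expect_near(peak_extract(cyc, g$recording$fx$values),
                gt$cycles$peak_fx[i], 0.05 * gt$cycles$peak_fx[i])
  }
})

test_that("Bland-Altman matches hand computation and is antisymmetric", {
  m <- c(10, 20, 30, 40)
  ba0 <- bland_altman(m, m)
  expect_equal(ba0$bias, 0)
  expect_equal(ba0$loa_high - ba0$loa_low, 0)
  ba_off <- bland_altman(m, m + 2)
  expect_equal(ba_off$bias, 2)
  expect_equal(ba_off$loa_high - ba_off$loa_low, 0)

  # d = {1, 2, 3, 4}: bias 2.5, SD = sqrt(5/3), LoA = (-0.0304, 5.0304)
  ba <- bland_altman(m, m + 1:4)
  expect_equal(ba$bias, 2.5)
  expect_equal(ba$sd_diff, sqrt(5 / 3), tolerance = 1e-12)
  expect_equal(ba$loa_low, 2.5 - 1.96 * sqrt(5 / 3), tolerance = 1e-12)
  expect_equal(ba$loa_high, 2.5 + 1.96 * sqrt(5 / 3), tolerance = 1e-12)
  expect_near(c(ba$loa_low, ba$loa_high), c(-0.0304, 5.0304), 1e-3)

  swapped <- bland_altman(m + 1:4, m)
  expect_equal(swapped$bias, -ba$bias)
  expect_equal(swapped$loa_low, -ba$loa_high)
  expect_equal(swapped$loa_high, -ba$loa_low)
  expect_error(bland_altman(1, 2), "n >= 2")
})

test_that("peak ANOVA equals the squared pooled t and textbook sums of squares", {
  identical_groups <- anova_peaks(c(1, 2, 3), c(1, 2, 3))
  expect_equal(unname(identical_groups["F"]), 0, tolerance = 1e-12)
  expect_equal(unname(identical_groups["p"]), 1, tolerance = 1e-12)

  m <- c(1, 2, 3, 4); p <- c(2, 3, 4, 7)
  out <- anova_peaks(m, p)
  # independent hand computation of one-way ANOVA sums of squares
  grand <- mean(c(m, p))
  ssb <- 4 * (mean(m) - grand)^2 + 4 * (mean(p) - grand)^2
  ssw <- sum((m - mean(m))^2) + sum((p - mean(p))^2)
  f_hand <- (ssb / 1) / (ssw / 6)
  expect_equal(unname(out["F"]), f_hand, tolerance = 1e-12)
  # squared pooled two-sample t
  tt <- stats::t.test(m, p, var.equal = TRUE)
  expect_equal(unname(out["F"]), unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(unname(out["p"]), tt$p.value, tolerance = 1e-10)

  # separation limit: tiny within-group jitter drives p toward zero
  sep <- anova_peaks(c(0, 0, 0, 0) + 1e-9 * (1:4), c(1, 1, 1, 1) + 1e-9 * (1:4))
  expect_lt(unname(sep["p"]), 1e-10)
  expect_error(anova_peaks(c(1, 1), c(2, 2)), "zero variance")
})

test_that("report tables lay out subjects and recompute their mean row", {
  res <- expand.grid(subject = 1:11, side = c("right", "left"),
                     channel = c("fx", "fy", "mz"), stringsAsFactors = FALSE)
  set.seed(52)
  res$rmse <- runif(nrow(res), 1, 10)
  res$mae <- res$rmse * runif(nrow(res), 0.6, 0.99)
  tab <- report_tables(res)
  expect_equal(nrow(tab), 12L)                 # 11 subjects + mean row
  expect_equal(tab$subject[12], "Mean")
  # independent recomputation of a few cells and the mean row
  cell <- res$rmse[res$subject == 3 & res$side == "left" & res$channel == "fy"]
  expect_equal(tab[3, "fy_rmse_left"], cell)
  for (col in names(tab)[-1]) {
    expect_equal(tab[12, col], mean(tab[1:11, col]), tolerance = 1e-12)
  }
  # constant metrics give a constant mean
  res2 <- res; res2$rmse <- 5; res2$mae <- 4
  tab2 <- report_tables(res2)
  expect_true(all(tab2[12, grep("rmse", names(tab2))] == 5))
  # CSV round trip
  stem <- file.path(tempdir(), "report")
  write_report(tab, stem)
  back <- utils::read.csv(paste0(stem, ".csv"), check.names = FALSE)
  expect_equal(back$fx_rmse_right, tab$fx_rmse_right, tolerance = 1e-9)
})
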