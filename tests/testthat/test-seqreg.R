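# BiLSTM sequence regressor: gradients, contracts, learnability

smooth_seq <- function(Tn = 60) {
  x <- matrix(rnorm(2 * Tn), 2, Tn)
  x[1, ] <- as.numeric(stats::filter(x[1, ], rep(1 / 5, 5), sides = 2))
  x[1, is.na(x[1, ])] <- 0
  x
}

test_that("analytic BPTT gradients match finite differences", {
  set.seed(40)
  cfg <- seqreg_config(n_layers = 2, hidden_units = 3, epochs = 1, seed = 40)
  params <- wheelkin:::seqreg_init_params(cfg)
  X <- matrix(rnorm(2 * 7), 2, 7)
  y <- rnorm(7)
  fwd <- wheelkin:::seqreg_forward(params, cfg, X)
  g <- wheelkin:::seqreg_backward(params, cfg, fwd, y)
  lossfn <- function(p) {
    mean((wheelkin:::seqreg_forward(p, cfg, X)$yhat - y)^2)
  }
  h <- 1e-6
  worst <- 0
  for (nm in names(params)) {
    for (k in sample(length(params[[nm]]), min(4, length(params[[nm]])))) {
      p1 <- params; p1[[nm]][k] <- p1[[nm]][k] + h
      p2 <- params; p2[[nm]][k] <- p2[[nm]][k] - h
      num <- (lossfn(p1) - lossfn(p2)) / (2 * h)
      rel <- abs(num - g[[nm]][k]) / max(abs(num), abs(g[[nm]][k]), 1e-6)
      worst <- max(worst, rel)
    }
  }
  expect_lt(worst, 1e-4)
})

test_that("prediction keeps sequence length and is deterministic", {
  set.seed(41)
  cfg <- seqreg_config(n_layers = 1, hidden_units = 4, epochs = 2, seed = 41,
                       batch_size = 4)
  train <- lapply(1:6, function(i) { x <- smooth_seq(40); list(x = x, y = x[1, ]) })
  val <- lapply(1:2, function(i) { x <- smooth_seq(40); list(x = x, y = x[1, ]) })
  mod <- seqreg_train(cfg, train, val)
  for (Tn in c(13, 40, 99)) {
    x <- matrix(rnorm(2 * Tn), 2, Tn)
    expect_length(predict(mod, x), Tn)
    expect_identical(predict(mod, x), predict(mod, x))
  }
  expect_error(predict(mod, matrix(0, 3, 10)), "2 x T")
  expect_equal(nrow(mod$curves), cfg$epochs)
  expect_true(all(is.finite(as.matrix(mod$curves))))
})

test_that("training is reproducible for a fixed seed", {
  train <- lapply(1:5, function(i) { x <- smooth_seq(30); list(x = x, y = x[1, ]) })
  val <- train[1:2]
  cfg <- seqreg_config(n_layers = 1, hidden_units = 4, epochs = 3, seed = 7,
                       batch_size = 2)
  m1 <- seqreg_train(cfg, train, val)
  m2 <- seqreg_train(cfg, train, val)
  expect_identical(m1$curves$val_rmse, m2$curves$val_rmse)
  expect_identical(m1$params, m2$params)
})

test_that("a reduced network learns an identity channel", {
  set.seed(42)
  train <- lapply(1:30, function(i) { x <- smooth_seq(60); list(x = x, y = x[1, ]) })
  val <- lapply(1:8, function(i) { x <- smooth_seq(60); list(x = x, y = x[1, ]) })
  cfg <- seqreg_config(n_layers = 1, hidden_units = 8, epochs = 60, seed = 2,
                       lr = 0.02, batch_size = 8)
  mod <- seqreg_train(cfg, train, val)
  expect_lt(mod$curves$val_rmse[nrow(mod$curves)], 0.05)
})

test_that("a zero-variance target trains to a near-constant prediction", {
  set.seed(43)
  train <- lapply(1:6, function(i) list(x = smooth_seq(30), y = rep(2, 30)))
  cfg <- seqreg_config(n_layers = 1, hidden_units = 4, epochs = 150, seed = 3,
                       lr = 0.05, batch_size = 6)
  mod <- seqreg_train(cfg, train, train[1:2])
  expect_lt(mod$curves$val_rmse[nrow(mod$curves)], 0.1)
})

test_that("datasets pair one input per target with matching lengths", {
  g <- generate_recording(gen_params(seed = 44, n_cycles = 10))
  rec <- g$recording
  aligned <- recording("right", accel_norm = rec$accel_norm,
                       gyro_norm = rec$gyro_norm,
                       fx = resample(rec$fx, 120), fy = resample(rec$fy, 120),
                       mz = resample(rec$mz, 120))
  lo <- g$truth$kick_imu[1] + 120
  hi <- g$truth$kick_imu[2] - 120
  cyc <- segment_cycles(ts_crop(aligned$mz, lo, hi))
  for (col in c("start", "end", "ext_start", "ext_end")) {
    cyc[[col]] <- cyc[[col]] + lo - 1L
  }
  ds <- seqreg_make_dataset(aligned, cyc, "mz")
  expect_length(ds, nrow(cyc))
  for (s in ds) {
    expect_equal(ncol(s$x), length(s$y))
    expect_equal(nrow(s$x), 2L)
  }
  # deployment mode: no kinetics, no dataset
  depl <- recording("right", accel_norm = rec$accel_norm,
                    gyro_norm = rec$gyro_norm)
  expect_error(seqreg_make_dataset(depl, cyc, "mz"), "no measured kinetics")
})

test_that("peak-stratified split and LOSO partition sizes are right", {
  set.seed(45)
  ds <- lapply(1:40, function(i) list(x = smooth_seq(20), y = rnorm(20, sd = i)))
  sp <- seqreg_split(ds, frac = 0.8, seed = 1)
  expect_length(sp$train, 32)
  expect_length(sp$val, 8)
  # peak homogeneity: train and val quartile composition stays balanced
  pk <- vapply(ds, function(s) max(s$y), numeric(1))
  qr <- cut(rank(pk, ties.method = "first"), 4, labels = FALSE)
  pk_tr <- vapply(sp$train, function(s) max(s$y), numeric(1))
  counts <- table(qr[match(pk_tr, pk)])
  expect_true(all(counts == 8))

  subj <- rep(1:11, each = 30)
  lo <- loso_split(subj, 4)
  expect_length(lo$test, 30)
  expect_length(lo$train, 300)
  expect_error(loso_split(subj, 99), "not present")
})
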