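#' Sequence-regressor configuration
#'
#' Configuration of the bidirectional LSTM sequence-to-sequence regressor:
#' stacked BiLSTM layers followed by a per-sample fully connected readout,
#' trained with Adam on mean squared error. The full-scale configuration is
#' 3 layers of 400 hidden units for 300 epochs with an 80/20 train/validation
#' split; reduced sizes train in seconds on a CPU and go through the same
#' code path.
#'
#' @param n_layers Number of stacked BiLSTM layers (>= 1).
#' @param hidden_units Hidden state size per direction.
#' @param epochs Training epochs.
#' @param train_val_split Fraction of sequences used for training.
#' @param seed RNG seed; training is deterministic given the seed.
#' @param lr Adam learning rate.
#' @param batch_size Sequences per gradient step.
#' @param n_inputs Input channels (acceleration and angular-velocity norms).
#' @return A list of class `seqreg_config`.
#' @export
seqreg_config <- function(n_layers = 3L, hidden_units = 400L, epochs = 300L,
                          train_val_split = 0.8, seed = 1L, lr = 1e-3,
                          batch_size = 16L, n_inputs = 2L) {
  stopifnot(n_layers >= 1L, hidden_units >= 1L, epochs >= 1L,
            train_val_split > 0, train_val_split < 1)
  structure(as.list(environment()), class = "seqreg_config")
}

sigm <- function(x) 1 / (1 + exp(-x))

# parameters held as a flat named list of arrays; gate row order is i, f, g, o
seqreg_init_params <- function(cfg) {
  H <- cfg$hidden_units
  params <- list()
  d_in <- cfg$n_inputs
  for (l in seq_len(cfg$n_layers)) {
    for (dir in c("f", "b")) {
      r <- 1 / sqrt(H)
      key <- function(nm) sprintf("l%d.%s.%s", l, dir, nm)
      params[[key("W")]] <- matrix(stats::runif(4 * H * d_in, -r, r), 4 * H, d_in)
      params[[key("U")]] <- matrix(stats::runif(4 * H * H, -r, r), 4 * H, H)
      b <- numeric(4 * H)
      b[(H + 1):(2 * H)] <- 1            # forget-gate bias
      params[[key("b")]] <- b
    }
    d_in <- 2L * H
  }
  r <- 1 / sqrt(2 * H)
  params[["out.W"]] <- matrix(stats::runif(2 * H, -r, r), 1, 2 * H)
  params[["out.b"]] <- 0
  params
}

lstm_forward <- function(W, U, b, X) {
  Tn <- ncol(X)
  Z <- W %*% X + b                      # recurrent part added per step
  nH <- nrow(U) %/% 4L
  I <- F_ <- G <- O <- C <- Hs <- matrix(0, nH, Tn)
  h <- numeric(nH); c <- numeric(nH)
  ih <- 1:nH; fh <- nH + ih; gh <- 2 * nH + ih; oh <- 3 * nH + ih
  for (t in seq_len(Tn)) {
    z <- Z[, t] + U %*% h
    i <- sigm(z[ih]); f <- sigm(z[fh]); g <- tanh(z[gh]); o <- sigm(z[oh])
    c <- f * c + i * g
    h <- o * tanh(c)
    I[, t] <- i; F_[, t] <- f; G[, t] <- g; O[, t] <- o
    C[, t] <- c; Hs[, t] <- h
  }
  list(X = X, I = I, F = F_, G = G, O = O, C = C, H = Hs)
}

lstm_backward <- function(W, U, cache, dH) {
  nH <- nrow(cache$H)
  Tn <- ncol(cache$H)
  dW <- matrix(0, nrow(W), ncol(W))
  dU <- matrix(0, nrow(U), ncol(U))
  db <- numeric(nrow(W))
  dX <- matrix(0, ncol(W), Tn)
  dh_next <- numeric(nH); dc_next <- numeric(nH)
  for (t in seq(Tn, 1L)) {
    i <- cache$I[, t]; f <- cache$F[, t]; g <- cache$G[, t]; o <- cache$O[, t]
    c <- cache$C[, t]
    c_prev <- if (t > 1L) cache$C[, t - 1L] else numeric(nH)
    h_prev <- if (t > 1L) cache$H[, t - 1L] else numeric(nH)
    tc <- tanh(c)
    dh <- dH[, t] + dh_next
    dc <- dh * o * (1 - tc^2) + dc_next
    dz <- c(dc * g * i * (1 - i),
            dc * c_prev * f * (1 - f),
            dc * i * (1 - g^2),
            dh * tc * o * (1 - o))
    dW <- dW + tcrossprod(dz, cache$X[, t])
    dU <- dU + tcrossprod(dz, h_prev)
    db <- db + dz
    dX[, t] <- crossprod(W, dz)
    dh_next <- as.numeric(crossprod(U, dz))
    dc_next <- dc * f
  }
  list(dW = dW, dU = dU, db = db, dX = dX)
}

# full forward pass; returns per-layer caches and the prediction
seqreg_forward <- function(params, cfg, X) {
  caches <- vector("list", cfg$n_layers)
  inp <- X
  for (l in seq_len(cfg$n_layers)) {
    kf <- sprintf("l%d.f.", l); kb <- sprintf("l%d.b.", l)
    cf <- lstm_forward(params[[paste0(kf, "W")]], params[[paste0(kf, "U")]],
                       params[[paste0(kf, "b")]], inp)
    rev_idx <- rev(seq_len(ncol(inp)))
    cb <- lstm_forward(params[[paste0(kb, "W")]], params[[paste0(kb, "U")]],
                       params[[paste0(kb, "b")]], inp[, rev_idx, drop = FALSE])
    inp <- rbind(cf$H, cb$H[, rev_idx, drop = FALSE])
    caches[[l]] <- list(f = cf, b = cb)
  }
  yhat <- as.numeric(params[["out.W"]] %*% inp + params[["out.b"]])
  list(caches = caches, top = inp, yhat = yhat)
}

# gradients of the per-sequence MSE; returns flat list matching params
seqreg_backward <- function(params, cfg, fwd, y) {
  Tn <- length(y)
  dyhat <- matrix(2 * (fwd$yhat - y) / Tn, 1, Tn)
  grads <- list()
  grads[["out.W"]] <- dyhat %*% t(fwd$top)
  grads[["out.b"]] <- sum(dyhat)
  dTop <- crossprod(params[["out.W"]], dyhat)
  for (l in seq(cfg$n_layers, 1L)) {
    H <- cfg$hidden_units
    rev_idx <- rev(seq_len(Tn))
    cf <- fwd$caches[[l]]$f; cb <- fwd$caches[[l]]$b
    kf <- sprintf("l%d.f.", l); kb <- sprintf("l%d.b.", l)
    bf <- lstm_backward(params[[paste0(kf, "W")]], params[[paste0(kf, "U")]],
                        cf, dTop[1:H, , drop = FALSE])
    bb <- lstm_backward(params[[paste0(kb, "W")]], params[[paste0(kb, "U")]],
                        cb, dTop[(H + 1):(2 * H), rev_idx, drop = FALSE])
    grads[[paste0(kf, "W")]] <- bf$dW
    grads[[paste0(kf, "U")]] <- bf$dU
    grads[[paste0(kf, "b")]] <- bf$db
    grads[[paste0(kb, "W")]] <- bb$dW
    grads[[paste0(kb, "U")]] <- bb$dU
    grads[[paste0(kb, "b")]] <- bb$db
    dTop <- bf$dX + bb$dX[, rev_idx, drop = FALSE]
  }
  grads
}

seqreg_loss <- function(params, cfg, set) {
  tot <- 0; n <- 0L
  for (s in set) {
    yhat <- seqreg_forward(params, cfg, s$x)$yhat
    tot <- tot + sum((yhat - s$y)^2)
    n <- n + length(s$y)
  }
  tot / n
}

#' Build sequence-regression pairs from a recording
#'
#' One training pair per extended push-cycle window: a 2-channel input
#' (RMS-normalized acceleration and angular-velocity norms) and the
#' RMS-normalized target channel. No generic-pattern input is used.
#'
#' @param rec An aligned [recording()] with kinetics.
#' @param cycles A [segment_cycles()] result.
#' @param channel Target channel.
#' @param window RMS window passed to [rms_normalize()].
#' @return A `seqreg_dataset`: list of `list(x, y, factor)` with `x` a
#'   `2 x T` matrix and `y` a length-`T` target.
#' @export
seqreg_make_dataset <- function(rec, cycles, channel = c("mz", "fx", "fy"),
                                window = c("push", "extended")) {
  channel <- match.arg(channel)
  window <- match.arg(window)
  if (is.null(rec[[channel]])) {
    stop("seqreg_make_dataset: recording carries no measured kinetics",
         call. = FALSE)
  }
  out <- lapply(cycle_list(cycles), function(cyc) {
    acc <- rms_normalize(cyc, rec$accel_norm, window)$values
    gyr <- rms_normalize(cyc, rec$gyro_norm, window)$values
    tgt <- rms_normalize(cyc, rec[[channel]], window)
    list(x = rbind(acc, gyr), y = tgt$values, factor = tgt$factor, cycle = cyc)
  })
  structure(out, class = "seqreg_dataset", channel = channel)
}

#' @export
`[.seqreg_dataset` <- function(x, i) {
  structure(unclass(x)[i], class = "seqreg_dataset", channel = attr(x, "channel"))
}

#' Peak-stratified train/validation split
#'
#' Splits sequences into training and validation sets while keeping the
#' distribution of peak target amplitudes homogeneous between the two:
#' sequences are stratified by peak-amplitude quartile and each stratum is
#' split at the requested ratio.
#'
#' @param dataset A [seqreg_make_dataset()] result (or any list of pairs).
#' @param frac Training fraction.
#' @param seed RNG seed for the within-stratum draw.
#' @return List with `train` and `val` subsets.
#' @export
seqreg_split <- function(dataset, frac = 0.8, seed = 1L) {
  peaks <- vapply(dataset, function(s) max(s$y), numeric(1))
  qr <- cut(rank(peaks, ties.method = "first"), breaks = 4, labels = FALSE)
  set.seed(seed)
  train_idx <- integer(0)
  for (g in sort(unique(qr))) {
    idx <- which(qr == g)
    n_tr <- max(1L, round(frac * length(idx)))
    train_idx <- c(train_idx, sort(sample(idx, n_tr)))
  }
  train_idx <- sort(train_idx)
  list(train = dataset[train_idx],
       val = dataset[setdiff(seq_along(dataset), train_idx)])
}

#' Train the BiLSTM sequence regressor
#'
#' Minimizes per-sample MSE with Adam over mini-batches of whole sequences.
#' Returns the trained parameters together with per-epoch loss and RMSE
#' curves for the training and validation sets, so successful (converging,
#' non-diverging) training is assertable. Non-finite loss aborts with the
#' offending epoch.
#'
#' @param cfg A [seqreg_config()].
#' @param train_set,val_set Lists of `list(x, y)` pairs.
#' @return An object of class `seqreg_model` with `params`, `config` and
#'   `curves` (data frame, one row per epoch).
#' @export
seqreg_train <- function(cfg, train_set, val_set) {
  stopifnot(inherits(cfg, "seqreg_config"),
            length(train_set) >= 1L, length(val_set) >= 1L)
  set.seed(cfg$seed)
  params <- seqreg_init_params(cfg)
  m <- lapply(params, function(p) p * 0)
  v <- lapply(params, function(p) p * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  step <- 0L
  curves <- data.frame(epoch = seq_len(cfg$epochs), train_loss = NA_real_,
                       train_rmse = NA_real_, val_loss = NA_real_,
                       val_rmse = NA_real_)
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample(length(train_set))
    for (start in seq(1L, length(ord), by = cfg$batch_size)) {
      batch <- ord[start:min(start + cfg$batch_size - 1L, length(ord))]
      acc <- NULL
      for (j in batch) {
        s <- train_set[[j]]
        fwd <- seqreg_forward(params, cfg, s$x)
        g <- seqreg_backward(params, cfg, fwd, s$y)
        acc <- if (is.null(acc)) g else mapply(`+`, acc, g, SIMPLIFY = FALSE)
      }
      step <- step + 1L
      for (nm in names(params)) {
        gn <- acc[[nm]] / length(batch)
        m[[nm]] <- beta1 * m[[nm]] + (1 - beta1) * gn
        v[[nm]] <- beta2 * v[[nm]] + (1 - beta2) * gn^2
        mh <- m[[nm]] / (1 - beta1^step)
        vh <- v[[nm]] / (1 - beta2^step)
        params[[nm]] <- params[[nm]] - cfg$lr * mh / (sqrt(vh) + eps)
      }
    }
    tl <- seqreg_loss(params, cfg, train_set)
    vl <- seqreg_loss(params, cfg, val_set)
    if (!is.finite(tl) || !is.finite(vl)) {
      stop(sprintf("seqreg_train: non-finite loss at epoch %d", ep),
           call. = FALSE)
    }
    curves[ep, -1] <- c(tl, sqrt(tl), vl, sqrt(vl))
  }
  structure(list(params = params, config = cfg, curves = curves),
            class = "seqreg_model")
}

#' @export
print.seqreg_model <- function(x, ...) {
  last <- x$curves[nrow(x$curves), ]
  cat(sprintf(
    "<seqreg_model> %d x %d BiLSTM, %d epochs; final train RMSE %.4g, val RMSE %.4g\n",
    x$config$n_layers, x$config$hidden_units, x$config$epochs,
    last$train_rmse, last$val_rmse))
  invisible(x)
}

#' Predict a normalized force/moment sequence
#'
#' @param object A trained [seqreg_train()] model.
#' @param x A `2 x T` input matrix (normalized acceleration and
#'   angular-velocity norms) or a dataset entry with an `$x` field.
#' @param ... Unused.
#' @return Numeric vector of length `T`.
#' @export
predict.seqreg_model <- function(object, x, ...) {
  if (is.list(x) && !is.null(x$x)) x <- x$x
  if (!is.matrix(x) || nrow(x) != object$config$n_inputs) {
    stop(sprintf("predict: input must be a %d x T matrix",
                 object$config$n_inputs), call. = FALSE)
  }
  seqreg_forward(object$params, object$config, x)$yhat
}

#' Leave-one-subject-out index split
#'
#' @param subject_ids Vector of per-sequence subject labels.
#' @param held_out The subject to hold out.
#' @return List with `train` and `test` index vectors.
#' @export
loso_split <- function(subject_ids, held_out) {
  test <- which(subject_ids == held_out)
  if (!length(test)) {
    stop("loso_split: held-out subject not present", call. = FALSE)
  }
  list(train = which(subject_ids != held_out), test = test)
}
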