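# Independent scalar oracles, kept deliberately naive: they re-derive each
# operation sample by sample and never share code with the implementation.

# piecewise-linear map evaluated one sample at a time, segment by segment
oracle_nl <- function(nl, x) {
  bp <- nl$breakpoints; v <- nl$values
  m <- length(bp)
  vapply(x, function(xi) {
    if (xi <= bp[1]) {
      seg <- 1L
    } else if (xi >= bp[m]) {
      seg <- m - 1L
    } else {
      seg <- max(which(bp <= xi))
      if (seg == m) seg <- m - 1L
    }
    sl <- (v[seg + 1L] - v[seg]) / (bp[seg + 1L] - bp[seg])
    v[seg] + sl * (xi - bp[seg])
  }, numeric(1))
}

# direct difference equation a0 y[t] = sum b u - sum a y, zero initial state
oracle_filter <- function(b, a, u) {
  n <- length(u)
  y <- numeric(n)
  for (t in seq_len(n)) {
    acc <- 0
    for (k in seq_along(b)) {
      if (t - k + 1L >= 1L) acc <- acc + b[k] * u[t - k + 1L]
    }
    for (k in seq_along(a)[-1]) {
      if (t - k + 1L >= 1L) acc <- acc - a[k] * y[t - k + 1L]
    }
    y[t] <- acc / a[1]
  }
  y
}

# explicit three-stage composition of the MISO Hammerstein-Wiener structure
oracle_hw <- function(model, inputs) {
  v <- 0
  for (i in 1:3) {
    w <- oracle_nl(model$input_nl[[i]], inputs[[i]])
    ba <- lb_coeffs(model$linear[[i]])
    v <- v + oracle_filter(ba$b, ba$a, w)
  }
  oracle_nl(model$output_nl, v)
}

# random stable linear block with n_p poles and n_z zeros inside |z| < 0.95
random_block <- function(n_p, n_z, gain = NULL) {
  rand_sections <- function(n) {
    secs <- list()
    while (n > 0L) {
      if (n >= 2L && stats::runif(1) < 0.5) {
        r <- stats::runif(1, 0.1, 0.95)
        th <- stats::runif(1, 0.1, pi - 0.1)
        secs[[length(secs) + 1L]] <- c(1, -2 * r * cos(th), r^2)
        n <- n - 2L
      } else {
        secs[[length(secs) + 1L]] <- c(1, -stats::runif(1, -0.95, 0.95))
        n <- n - 1L
      }
    }
    secs
  }
  linear_block(gain %||% stats::runif(1, -2, 2),
               num = rand_sections(n_z), den = rand_sections(n_p))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# random gentle piecewise nonlinearity around the identity
random_nl <- function(bp = c(-1.5, -0.2, 0.8, 2)) {
  piecewise_nl(bp, bp + stats::rnorm(length(bp), 0, 0.3))
}

random_hw_model <- function(orders = list(c(2, 1), c(2, 1), c(2, 1)),
                            channel = "mz") {
  hw_model(
    input_nl = list(random_nl(), random_nl(), random_nl()),
    linear = lapply(orders, function(o) random_block(o[1], o[2])),
    output_nl = random_nl(c(-3, -1, 1, 3)),
    channel = channel)
}

# rectangular moment pulse train: `n` pulses of the given height/duty/period
pulse_train_mz <- function(n = 10, height = 10, duty = 0.3, period = 120,
                           rate = 120, pad = 60) {
  x <- numeric(pad)
  push <- round(duty * period)
  for (k in seq_len(n)) {
    x <- c(x, rep(height, push), numeric(period - push))
  }
  time_series(c(x, numeric(pad)), rate = rate, units = "N.m")
}

# smooth random cycle inputs for identification experiments
make_hw_cycles <- function(model, n_cycles, len = 150, noise_sd = 0) {
  cycles <- lapply(seq_len(n_cycles), function(i) {
    u <- lapply(1:3, function(j) {
      s <- as.numeric(stats::filter(stats::rnorm(len), rep(1 / 8, 8), sides = 1))
      s[is.na(s)] <- 0
      s
    })
    y <- hw_simulate(model, u)
    list(inputs = u, target = y + stats::rnorm(len, 0, noise_sd))
  })
  structure(cycles, class = "hw_dataset", channel = model$channel)
}

expect_near <- function(object, expected, tol) {
  expect_true(max(abs(object - expected)) < tol,
              label = sprintf("max|diff| = %.3g (tol %.3g)",
                              max(abs(object - expected)), tol))
}
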