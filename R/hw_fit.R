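#' Build a Hammerstein-Wiener training dataset from a recording
#'
#' Extracts, for every push cycle, the three RMS-normalized input sequences
#' (acceleration norm, angular-velocity norm, generic-pattern channel) and
#' the RMS-normalized target channel over the cycle's 140 % extended window.
#' Input channels are normalized with the same per-cycle push-phase RMS
#' scheme as the kinetic channels.
#'
#' @param rec An aligned [recording()] with kinetics present.
#' @param cycles A [segment_cycles()] result on the recording's Mz.
#' @param pattern A [compute_generic_pattern()] of the target channel.
#' @param channel Target channel: `"fx"`, `"fy"` or `"mz"`.
#' @param window RMS window passed to [rms_normalize()].
#' @param require_target Set `FALSE` for deployment mode: the target channel
#'   may then be absent and the dataset carries inputs only (`target = NULL`,
#'   `factor = NA`).
#' @return An `hw_dataset`: list of cycles, each holding `inputs` (list of 3
#'   numeric sequences), `target`, and the de-normalization `factor` of the
#'   target channel.
#' @export
hw_make_dataset <- function(rec, cycles, pattern, channel = c("mz", "fx", "fy"),
                            window = c("push", "extended"),
                            require_target = TRUE) {
  channel <- match.arg(channel)
  window <- match.arg(window)
  if (is.null(rec[[channel]]) && require_target) {
    stop("hw_make_dataset: recording carries no measured kinetics",
         call. = FALSE)
  }
  pat_chan <- pattern_as_input(pattern, cycles,
                               n = length(rec$accel_norm$values),
                               rate = rec$accel_norm$rate)
  out <- lapply(cycle_list(cycles), function(cyc) {
    acc <- rms_normalize(cyc, rec$accel_norm, window)
    gyr <- rms_normalize(cyc, rec$gyro_norm, window)
    tgt <- if (is.null(rec[[channel]])) list(values = NULL, factor = NA_real_)
           else rms_normalize(cyc, rec[[channel]], window)
    pat <- pat_chan$values[cyc$ext_start:(cyc$ext_end - 1L)]
    list(inputs = list(acc$values, gyr$values, pat),
         target = tgt$values, factor = tgt$factor, cycle = cyc)
  })
  structure(out, class = "hw_dataset", channel = channel)
}

#' @export
`[.hw_dataset` <- function(x, i) {
  structure(unclass(x)[i], class = "hw_dataset", channel = attr(x, "channel"))
}

#' Identification settings
#'
#' @param max_iter Maximum Levenberg-Marquardt iterations.
#' @param tol Relative training-error improvement below which iteration
#'   stops.
#' @param pole_limit Maximum pole magnitude enforced during identification
#'   (candidate poles outside are projected radially back inside).
#' @param lambda0 Initial LM damping.
#' @param nl_order Nodes per nonlinear bloc.
#' @param quantiles Breakpoint placement quantiles of the data distribution.
#' @param seed Stored for provenance (the fit itself is deterministic).
#' @return A list of class `hw_control`.
#' @export
hw_control <- function(max_iter = 50L, tol = 1e-6, pole_limit = 0.999,
                       lambda0 = 1e-3, nl_order = 4L,
                       quantiles = c(0.10, 0.37, 0.63, 0.90), seed = 1L) {
  structure(list(max_iter = max_iter, tol = tol, pole_limit = pole_limit,
                 lambda0 = lambda0, nl_order = nl_order, quantiles = quantiles,
                 seed = seed),
            class = "hw_control")
}

# strictly increasing breakpoints at the given quantiles of x
fit_breakpoints <- function(x, quantiles) {
  bp <- as.numeric(stats::quantile(x, quantiles, names = FALSE, type = 7))
  span <- max(diff(range(x)), 1e-6)
  for (i in seq_along(bp)[-1]) {
    if (bp[i] <= bp[i - 1]) bp[i] <- bp[i - 1] + 1e-3 * span
  }
  bp
}

## ---- parameter vector packing --------------------------------------------

hw_theta_layout <- function(order, nl_order) {
  p <- unlist(order[c("p1", "p2", "p3")], use.names = FALSE)
  q <- unlist(order[c("q1", "q2", "q3")], use.names = FALSE)
  sizes <- c(rbind(p, q + 1L), rep(nl_order, 4L))
  names(sizes) <- c(t(outer(1:3, c("a", "b"), function(i, s) paste0(s, i))),
                    paste0("nl", 1:3), "nlout")
  offs <- cumsum(c(0L, sizes))
  list(p = p, q = q, sizes = sizes, offsets = offs[-length(offs)],
       total = sum(sizes))
}

hw_theta_slice <- function(layout, name) {
  k <- match(name, names(layout$sizes))
  layout$offsets[k] + seq_len(layout$sizes[k])
}

hw_unpack <- function(theta, layout, bps, channel) {
  lin <- vector("list", 3L)
  nls <- vector("list", 3L)
  for (i in 1:3) {
    a <- c(1, theta[hw_theta_slice(layout, paste0("a", i))])
    b <- theta[hw_theta_slice(layout, paste0("b", i))]
    lin[[i]] <- list(a = a, b = b)
    nls[[i]] <- piecewise_nl(bps$input[[i]],
                             theta[hw_theta_slice(layout, paste0("nl", i))])
  }
  list(lin = lin, input_nl = nls,
       output_nl = piecewise_nl(bps$output, theta[hw_theta_slice(layout, "nlout")]),
       channel = channel)
}

hw_pack_model <- function(par, tol = 1e-6) {
  blocks <- lapply(par$lin, function(l) {
    b <- l$b
    if (abs(b[1]) < 1e-12) b[1] <- 1e-12  # keep the factored gain well defined
    lb_from_coeffs(b, l$a, tol = tol)
  })
  hw_model(par$input_nl, blocks, par$output_nl, channel = par$channel)
}

# shift a sequence right by k samples (zero fill)
shift_right <- function(x, k) {
  if (k == 0L) return(x)
  c(numeric(k), x[seq_len(length(x) - k)])
}

iir <- function(b, a, x) as.numeric(signal::filter(b, a, x))

# simulate the unpacked parameterization on one cycle; returns v and yhat
hw_sim_par <- function(par, inputs) {
  n <- length(inputs[[1]])
  v <- numeric(n)
  w <- vector("list", 3L)
  for (i in 1:3) {
    w[[i]] <- nl_eval(par$input_nl[[i]], inputs[[i]])
    v <- v + iir(par$lin[[i]]$b, par$lin[[i]]$a, w[[i]])
  }
  list(v = v, yhat = nl_eval(par$output_nl, v), w = w)
}

# radially shrink the roots of a monic polynomial in z^-1 into |z| <= limit
project_poles <- function(a, limit) {
  if (length(a) <= 1L) return(a)
  r <- polyroot(rev(a))
  mx <- max(Mod(r))
  if (mx <= limit) return(a)
  rho <- limit / mx
  a * rho^(seq_along(a) - 1L)
}

## ---- residuals and Jacobian ----------------------------------------------

hw_residuals <- function(par, data) {
  unlist(lapply(data, function(cyc) {
    sim <- hw_sim_par(par, cyc$inputs)
    cyc$target - sim$yhat
  }), use.names = FALSE)
}

hw_jacobian <- function(par, data, layout, bps) {
  rows <- lapply(data, function(cyc) {
    sim <- hw_sim_par(par, cyc$inputs)
    n <- length(sim$v)
    J <- matrix(0, n, layout$total)
    dfo <- nl_deriv(par$output_nl, sim$v)
    for (i in 1:3) {
      a <- par$lin[[i]]$a; b <- par$lin[[i]]$b
      xi <- iir(b, a, sim$w[[i]])           # block output
      gi <- iir(1, a, sim$w[[i]])           # w filtered by 1/A
      # d v / d a_ik = -z^-k (1/A) x_i ; d v / d b_ij = z^-j (1/A) w_i
      ja <- hw_theta_slice(layout, paste0("a", i))
      for (k in seq_along(ja)) {
        J[, ja[k]] <- dfo * (-shift_right(iir(1, a, xi), k))
      }
      jb <- hw_theta_slice(layout, paste0("b", i))
      for (j in seq_along(jb)) {
        J[, jb[j]] <- dfo * shift_right(gi, j - 1L)
      }
      # d v / d input ordinate m = L_i basis_m(u_i)
      Bm <- nl_basis(bps$input[[i]], cyc$inputs[[i]])
      jn <- hw_theta_slice(layout, paste0("nl", i))
      for (m in seq_along(jn)) {
        J[, jn[m]] <- dfo * iir(b, a, Bm[, m])
      }
    }
    J[, hw_theta_slice(layout, "nlout")] <- nl_basis(bps$output, sim$v)
    -J  # residual is target - yhat
  })
  do.call(rbind, rows)
}

## ---- initialization -------------------------------------------------------

hw_init_theta <- function(data, layout, bps, pole_limit) {
  nl_order <- length(bps$output)
  theta <- numeric(layout$total)
  for (i in 1:3) theta[hw_theta_slice(layout, paste0("nl", i))] <- bps$input[[i]]
  theta[hw_theta_slice(layout, "nlout")] <- bps$output
  # per-block SISO ARX for the denominators (nonlinearities at identity)
  for (i in 1:3) {
    p <- layout$p[i]; q <- layout$q[i]
    X <- NULL; Y <- NULL
    for (cyc in data) {
      u <- cyc$inputs[[i]]; y <- cyc$target
      t0 <- max(p, q) + 1L
      if (t0 > length(y)) next
      rows <- t0:length(y)
      Xy <- sapply(1:p, function(k) y[rows - k])
      Xu <- sapply(0:q, function(j) u[rows - j])
      X <- rbind(X, cbind(Xy, Xu)); Y <- c(Y, y[rows])
    }
    cf <- tryCatch(stats::lm.fit(X, Y)$coefficients, error = function(e) NULL)
    cf[!is.finite(cf)] <- 0
    a <- c(1, if (is.null(cf)) numeric(p) else -cf[1:p])
    a <- project_poles(a, 0.95)
    theta[hw_theta_slice(layout, paste0("a", i))] <- a[-1]
  }
  # joint least squares over all numerators at the fixed denominators
  X <- NULL; Y <- NULL
  cols <- unlist(lapply(1:3, function(i) hw_theta_slice(layout, paste0("b", i))))
  for (cyc in data) {
    n <- length(cyc$target)
    Xc <- matrix(0, n, length(cols))
    col <- 0L
    for (i in 1:3) {
      a <- c(1, theta[hw_theta_slice(layout, paste0("a", i))])
      gi <- iir(1, a, cyc$inputs[[i]])
      for (j in 0:layout$q[i]) {
        col <- col + 1L
        Xc[, col] <- shift_right(gi, j)
      }
    }
    X <- rbind(X, Xc); Y <- c(Y, cyc$target)
  }
  cf <- tryCatch(stats::lm.fit(X, Y)$coefficients, error = function(e) NULL)
  if (is.null(cf)) cf <- rep(0.1, length(cols))
  cf[!is.finite(cf)] <- 0
  theta[cols] <- cf
  theta
}

## ---- the fit --------------------------------------------------------------

#' Identify a Hammerstein-Wiener model by prediction-error minimization
#'
#' Minimizes the mean squared one-pass simulation error over the training
#' cycles. Initialization is staged: nonlinearities start at identity,
#' denominators come from per-block equation-error (ARX) least squares and
#' numerators from a joint least squares at those denominators; the full
#' parameter vector (filter coefficients plus the ordinates of all four
#' nonlinear blocs at fixed, quantile-placed breakpoints) is then refined by
#' Levenberg-Marquardt with an analytic Jacobian. Accepted steps never
#' increase the training error; candidate poles outside `pole_limit` are
#' projected radially back inside the unit disc at every step.
#'
#' @param data An [hw_make_dataset()] result (training cycles).
#' @param order One row of [enumerate_orders()]: `p1, q1, p2, q2, p3, q3`.
#' @param control An [hw_control()].
#' @return An object of class `hw_fit`: `model`, `order`, `train_error`
#'   (NRMSE), `trace` (error per accepted iteration), `converged`.
#' @export
hw_identify <- function(data, order, control = hw_control()) {
  stopifnot(inherits(data, "hw_dataset"), length(data) >= 1L)
  order <- as.list(order)
  layout <- hw_theta_layout(order, control$nl_order)
  channel <- attr(data, "channel") %||% "mz"
  all_in <- lapply(1:3, function(i) {
    unlist(lapply(data, function(cyc) cyc$inputs[[i]]), use.names = FALSE)
  })
  y_all <- unlist(lapply(data, function(cyc) cyc$target), use.names = FALSE)
  bps <- list(input = lapply(all_in, fit_breakpoints, quantiles = control$quantiles),
              output = fit_breakpoints(y_all, control$quantiles))
  y_rms <- sqrt(mean(y_all^2))

  theta <- hw_init_theta(data, layout, bps, control$pole_limit)
  sse <- function(th) {
    par <- hw_unpack(th, layout, bps, channel)
    r <- hw_residuals(par, data)
    if (!all(is.finite(r))) return(Inf)
    sum(r^2)
  }
  project_theta <- function(th) {
    for (i in 1:3) {
      sl <- hw_theta_slice(layout, paste0("a", i))
      th[sl] <- project_poles(c(1, th[sl]), control$pole_limit)[-1]
    }
    th
  }
  theta <- project_theta(theta)
  err <- sse(theta)
  if (!is.finite(err)) {
    stop("hw_identify: initialization diverged (non-finite error)", call. = FALSE)
  }
  lambda <- control$lambda0
  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(control$max_iter)) {
    par <- hw_unpack(theta, layout, bps, channel)
    r <- hw_residuals(par, data)
    J <- hw_jacobian(par, data, layout, bps)
    JtJ <- crossprod(J)
    g <- crossprod(J, r)
    improved <- FALSE
    for (k in 1:20) {
      step <- tryCatch(
        solve(JtJ + lambda * diag(diag(JtJ) + 1e-12), -g),
        error = function(e) NULL)
      if (!is.null(step)) {
        cand <- project_theta(theta + as.numeric(step))
        err_c <- sse(cand)
        if (is.finite(err_c) && err_c < err) {
          theta <- cand
          rel <- (err - err_c) / max(err, 1e-300)
          err <- err_c
          lambda <- max(lambda * 0.3, 1e-12)
          improved <- TRUE
          trace <- c(trace, err)
          if (rel < control$tol) converged <- TRUE
          break
        }
      }
      lambda <- lambda * 10
    }
    if (!improved || converged) {
      converged <- converged || !improved
      break
    }
  }
  nrmse <- if (y_rms > 1e-9) sqrt(err / length(y_all)) / y_rms
           else sqrt(err / length(y_all))
  model <- hw_pack_model(hw_unpack(theta, layout, bps, channel))
  structure(list(model = model, order = order, train_error = nrmse,
                 test_error = NA_real_, trace = trace, converged = converged,
                 control = control),
            class = "hw_fit")
}

#' @export
print.hw_fit <- function(x, ...) {
  cat(sprintf("<hw_fit> orders (p/q): %s; train NRMSE = %.4g%s\n",
              paste(sprintf("%d/%d",
                            unlist(x$order[c("p1", "p2", "p3")]),
                            unlist(x$order[c("q1", "q2", "q3")])),
                    collapse = ", "),
              x$train_error,
              if (is.na(x$test_error)) "" else sprintf(", test NRMSE = %.4g", x$test_error)))
  invisible(x)
}

#' Normalized RMS simulation error of a model on a dataset
#'
#' NRMSE = RMS(error) / RMS(target) over the concatenated cycles, with an
#' absolute-error fallback when the target RMS is below `1e-9`.
#'
#' @param model An [hw_model()].
#' @param data An [hw_make_dataset()] result.
#' @return Scalar NRMSE (dimensionless).
#' @export
hw_nrmse <- function(model, data) {
  err2 <- 0; y2 <- 0; n <- 0L
  for (cyc in data) {
    yhat <- hw_simulate(model, cyc$inputs)
    err2 <- err2 + sum((cyc$target - yhat)^2)
    y2 <- y2 + sum(cyc$target^2)
    n <- n + length(yhat)
  }
  y_rms <- sqrt(y2 / n)
  if (y_rms > 1e-9) sqrt(err2 / n) / y_rms else sqrt(err2 / n)
}

#' Exhaustive model-order grid search
#'
#' Fits every order specification on the training cycles, ranks by training
#' NRMSE (ties broken by fewer total linear parameters, then by
#' lexicographic spec order), retains the top `keep` models, and evaluates
#' their test NRMSE on the held-out cycles. Failed fits are skipped with
#' their reason recorded, never aborting the sweep.
#'
#' @param train,test [hw_make_dataset()] results (test may be `NULL`).
#' @param orders An [enumerate_orders()] data frame (any subset).
#' @param keep Number of top-ranked models to retain (clamped to the number
#'   of successful fits).
#' @param control An [hw_control()].
#' @param verbose Print a line per fit.
#' @return An object of class `hw_grid`: `results` data frame (orders,
#'   train/test NRMSE, parameter counts, status) and `models`, the retained
#'   [hw_fit()] objects in rank order.
#' @export
hw_grid_search <- function(train, test = NULL, orders, keep = 111L,
                           control = hw_control(), verbose = FALSE) {
  stopifnot(nrow(orders) >= 1L)
  fits <- vector("list", nrow(orders))
  res <- cbind(as.data.frame(orders),
               train_error = NA_real_, test_error = NA_real_,
               n_par = NA_integer_, rank = NA_integer_,
               status = NA_character_)
  for (i in seq_len(nrow(orders))) {
    fit <- tryCatch(hw_identify(train, orders[i, ], control),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      res$status[i] <- conditionMessage(fit)
      next
    }
    fits[[i]] <- fit
    res$train_error[i] <- fit$train_error
    res$n_par[i] <- count_parameters(orders[i, ])$linear
    res$status[i] <- "ok"
    if (verbose) {
      message(sprintf("[%d/%d] train NRMSE %.4g", i, nrow(orders),
                      fit$train_error))
    }
  }
  ok <- which(res$status == "ok")
  ord <- ok[order(res$train_error[ok], res$n_par[ok], ok)]
  res$rank[ord] <- seq_along(ord)
  kept <- ord[seq_len(min(keep, length(ord)))]
  for (i in kept) {
    if (!is.null(test)) {
      fits[[i]]$test_error <- hw_nrmse(fits[[i]]$model, test)
      res$test_error[i] <- fits[[i]]$test_error
    }
  }
  structure(list(results = res, models = fits[kept], keep = keep),
            class = "hw_grid")
}

#' @export
print.hw_grid <- function(x, ...) {
  ok <- sum(x$results$status == "ok", na.rm = TRUE)
  cat(sprintf("<hw_grid> %d orders fitted (%d ok), %d retained\n",
              nrow(x$results), ok, length(x$models)))
  if (length(x$models)) {
    cat("best: "); print(x$models[[1]])
  }
  invisible(x)
}
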