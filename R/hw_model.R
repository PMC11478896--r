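#' MISO Hammerstein-Wiener model
#'
#' Three single-input Hammerstein-Wiener branches summed before a shared
#' output nonlinearity: each input channel (wrist acceleration norm, wrist
#' angular-velocity norm, generic force/moment pattern) passes through its
#' own static piecewise nonlinearity and rational linear block; the branch
#' outputs are summed and mapped through the output nonlinearity. In total:
#' 4 nonlinear blocs and 3 linear blocs.
#'
#' @param input_nl List of 3 [piecewise_nl()] (acceleration, gyro, pattern).
#' @param linear List of 3 [linear_block()].
#' @param output_nl A [piecewise_nl()].
#' @param channel Output channel this model predicts: `"fx"`, `"fy"` or
#'   `"mz"`.
#' @return An object of class `hw_model`.
#' @export
hw_model <- function(input_nl, linear, output_nl, channel = c("mz", "fx", "fy")) {
  channel <- match.arg(channel)
  if (length(input_nl) != 3L || !all(vapply(input_nl, inherits, TRUE, "piecewise_nl"))) {
    stop("hw_model: input_nl must be a list of 3 piecewise_nl", call. = FALSE)
  }
  if (length(linear) != 3L || !all(vapply(linear, inherits, TRUE, "linear_block"))) {
    stop("hw_model: linear must be a list of 3 linear_block", call. = FALSE)
  }
  stopifnot(inherits(output_nl, "piecewise_nl"))
  structure(list(input_nl = input_nl, linear = linear, output_nl = output_nl,
                 channel = channel),
            class = "hw_model")
}

#' @export
print.hw_model <- function(x, ...) {
  orders <- vapply(x$linear, function(b) {
    sprintf("%dz/%dp", length(lb_coeffs(b)$b) - 1L, length(lb_coeffs(b)$a) - 1L)
  }, "")
  cat(sprintf("<hw_model> channel = %s; linear blocks: %s\n",
              x$channel, paste(orders, collapse = ", ")))
  invisible(x)
}

#' Simulate a MISO Hammerstein-Wiener model
#'
#' `y = f_out( sum_i L_i( f_i(u_i) ) )` with zero initial filter state.
#'
#' @param model An [hw_model()].
#' @param inputs List of 3 equal-length numeric sequences (acceleration
#'   norm, angular-velocity norm, generic pattern), all RMS-normalized.
#' @return Numeric sequence: the normalized (dimensionless) predicted
#'   force/moment channel.
#' @export
hw_simulate <- function(model, inputs) {
  stopifnot(inherits(model, "hw_model"))
  if (length(inputs) != 3L) {
    stop("hw_simulate: need exactly 3 input sequences", call. = FALSE)
  }
  inputs <- lapply(inputs, function(u) {
    if (inherits(u, "time_series")) u$values else as.numeric(u)
  })
  n <- unique(lengths(inputs))
  if (length(n) != 1L) {
    stop("hw_simulate: input sequences must have equal length", call. = FALSE)
  }
  v <- numeric(n)
  for (i in 1:3) {
    v <- v + lb_filter(model$linear[[i]], nl_eval(model$input_nl[[i]], inputs[[i]]))
  }
  nl_eval(model$output_nl, v)
}

#' Enumerate linear-block order combinations
#'
#' The exhaustive model-order grid: each of the `n_blocks` linear blocks may
#' have `p` poles, `p` in `1..max_poles`, and `q` zeros, `q` in `0..p-1`
#' (strictly fewer zeros than poles). The Cartesian product over blocks is
#' returned in deterministic lexicographic order (block 1 varies slowest).
#' For `max_poles = 6` and 3 blocks this yields `21^3 = 9261` combinations.
#'
#' @param max_poles Maximum pole count per block (>= 1).
#' @param n_blocks Number of linear blocks.
#' @return An `order_specs` data frame with columns `p1, q1, ..., pk, qk`.
#' @export
enumerate_orders <- function(max_poles = 6L, n_blocks = 3L) {
  if (!is.numeric(max_poles) || max_poles < 1L) {
    stop("enumerate_orders: max_poles must be >= 1", call. = FALSE)
  }
  opts <- do.call(rbind, lapply(seq_len(max_poles), function(p) {
    data.frame(p = p, q = 0:(p - 1L))
  }))
  idx <- as.matrix(expand.grid(rev(replicate(n_blocks, seq_len(nrow(opts)),
                                             simplify = FALSE)))[, n_blocks:1,
                                                                 drop = FALSE])
  out <- data.frame(row.names = seq_len(nrow(idx)))
  for (k in seq_len(n_blocks)) {
    out[[paste0("p", k)]] <- opts$p[idx[, k]]
    out[[paste0("q", k)]] <- opts$q[idx[, k]]
  }
  # lexicographic by (p1, q1, p2, q2, ...)
  out <- out[do.call(order, out), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("order_specs", "data.frame"))
}

#' Parameter budget of a model-order specification
#'
#' Counts the free parameters of the MISO Hammerstein-Wiener template:
#' 4 nonlinear blocs of order 4 give 16 nonlinear parameters; each linear
#' block contributes its pole plus zero count (at the full order of 6 poles
#' and 5 zeros per block this is `3 * (6 + 5) = 33`).
#'
#' @param order One row of [enumerate_orders()] (or any list with `p1, q1,
#'   p2, q2, p3, q3`), or an [hw_model()].
#' @param nl_order Nodes per nonlinear bloc.
#' @param n_nl Number of nonlinear blocs (3 input + 1 output).
#' @return List with `nonlinear` and `linear` parameter counts.
#' @export
count_parameters <- function(order, nl_order = 4L, n_nl = 4L) {
  if (inherits(order, "hw_model")) {
    lin <- sum(vapply(order$linear, function(b) {
      ba <- lb_coeffs(b)
      (length(ba$a) - 1L) + (length(ba$b) - 1L)
    }, numeric(1)))
    n_nl <- length(order$input_nl) + 1L
    nl_order <- length(order$output_nl$breakpoints)
    return(list(nonlinear = n_nl * nl_order, linear = lin))
  }
  ps <- grep("^p[0-9]+$", names(order), value = TRUE)
  qs <- grep("^q[0-9]+$", names(order), value = TRUE)
  lin <- sum(unlist(order[ps])) + sum(unlist(order[qs]))
  list(nonlinear = as.integer(n_nl * nl_order), linear = as.integer(lin))
}

#' Serialize / restore a Hammerstein-Wiener model
#'
#' Models are stored as JSON: gains, factored real first/second-order
#' numerator and denominator sections, and the breakpoints/ordinates of the
#' four nonlinear blocs. The round trip preserves simulation output exactly
#' (all numbers written at full precision).
#'
#' @param model An [hw_model()].
#' @param path File path.
#' @return `hw_save` invisibly returns `path`; `hw_load` returns the model.
#' @export
hw_save <- function(model, path) {
  stopifnot(inherits(model, "hw_model"))
  ser_nl <- function(nl) list(breakpoints = nl$breakpoints, values = nl$values)
  ser_lb <- function(b) list(gain = b$gain, num = b$num, den = b$den)
  obj <- list(channel = model$channel,
              input_nl = lapply(model$input_nl, ser_nl),
              linear = lapply(model$linear, ser_lb),
              output_nl = ser_nl(model$output_nl))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname hw_save
#' @export
hw_load <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  de_nl <- function(o) piecewise_nl(unlist(o$breakpoints), unlist(o$values))
  de_lb <- function(o) {
    linear_block(o$gain, lapply(o$num, unlist), lapply(o$den, unlist), tol = Inf)
  }
  hw_model(input_nl = lapply(obj$input_nl, de_nl),
           linear = lapply(obj$linear, de_lb),
           output_nl = de_nl(obj$output_nl),
           channel = obj$channel)
}
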