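#' Static piecewise-linear nonlinearity
#'
#' The memoryless nonlinear "bloc" of the Hammerstein-Wiener model: a
#' continuous piecewise-linear map through `(breakpoints[k], values[k])`
#' nodes with linear continuation of the end segments. The default order is
#' 4 (four nodes, i.e. four free shape parameters once the breakpoints are
#' fixed).
#'
#' @param breakpoints Strictly increasing abscissae.
#' @param values Ordinates at the breakpoints.
#' @return An object of class `piecewise_nl`.
#' @examples
#' f <- piecewise_nl(c(-1, 0, 1, 2), c(-1, 0, 1, 2))  # identity on its range
#' nl_eval(f, c(-5, 0.5, 10))
#' @export
piecewise_nl <- function(breakpoints, values) {
  breakpoints <- as.numeric(breakpoints)
  values <- as.numeric(values)
  if (length(breakpoints) < 2L || length(breakpoints) != length(values)) {
    stop("piecewise_nl: need matching breakpoints/values of length >= 2",
         call. = FALSE)
  }
  if (any(diff(breakpoints) <= 0)) {
    stop("piecewise_nl: breakpoints must be strictly increasing", call. = FALSE)
  }
  if (!all(is.finite(breakpoints)) || !all(is.finite(values))) {
    stop("piecewise_nl: non-finite node", call. = FALSE)
  }
  structure(list(breakpoints = breakpoints, values = values),
            class = "piecewise_nl")
}

#' Identity-configured piecewise nonlinearity
#' @param breakpoints Node abscissae; ordinates are set equal to them.
#' @return A `piecewise_nl` realizing f(x) = x everywhere.
#' @export
nl_identity <- function(breakpoints = c(-1, 0, 1, 2)) {
  piecewise_nl(breakpoints, breakpoints)
}

#' Evaluate a piecewise nonlinearity
#'
#' Pointwise, memoryless evaluation with linear extrapolation beyond the end
#' breakpoints.
#'
#' @param nl A [piecewise_nl()].
#' @param x Numeric vector.
#' @return Numeric vector `f(x)`.
#' @export
nl_eval <- function(nl, x) {
  stopifnot(inherits(nl, "piecewise_nl"))
  bp <- nl$breakpoints; v <- nl$values
  k <- findInterval(x, bp, all.inside = TRUE)
  slope <- (v[k + 1L] - v[k]) / (bp[k + 1L] - bp[k])
  v[k] + slope * (x - bp[k])
}

# derivative of the map at x (piecewise constant; right-continuous at nodes)
nl_deriv <- function(nl, x) {
  bp <- nl$breakpoints; v <- nl$values
  k <- findInterval(x, bp, all.inside = TRUE)
  (v[k + 1L] - v[k]) / (bp[k + 1L] - bp[k])
}

# hat-function basis: column j is d f(x) / d values[j] (f is linear in the
# ordinates at fixed breakpoints)
nl_basis <- function(breakpoints, x) {
  m <- length(breakpoints)
  k <- findInterval(x, breakpoints, all.inside = TRUE)
  w <- (x - breakpoints[k]) / (breakpoints[k + 1L] - breakpoints[k])
  B <- matrix(0, length(x), m)
  B[cbind(seq_along(x), k)] <- 1 - w
  B[cbind(seq_along(x), k + 1L)] <- w
  B
}

#' Rational z-domain linear block
#'
#' A causal discrete-time filter `H(z) = gain * B(z^-1) / A(z^-1)` stored in
#' factored form: real first/second-order sections with unit leading
#' coefficient, mirroring the conventional factored notation for identified
#' transfer functions. Poles must satisfy `|pole| <= 1 + tol` (marginal
#' stability is tolerated for finite-horizon simulation of published
#' fixtures; identification itself constrains poles strictly inside the unit
#' circle).
#'
#' @param gain Scalar gain (the leading numerator coefficient).
#' @param num List of numerator section coefficient vectors, each `c(1, a1)`
#'   or `c(1, a1, a2)` in powers of `z^-1`; may be empty (no zeros).
#' @param den List of denominator section coefficient vectors, same form.
#' @param tol Pole-magnitude tolerance beyond the unit circle.
#' @return An object of class `linear_block`.
#' @export
linear_block <- function(gain, num = list(), den = list(), tol = 1e-6) {
  check_sections <- function(s, what) {
    for (sec in s) {
      if (!is.numeric(sec) || !length(sec) %in% c(2L, 3L) || sec[1] != 1) {
        stop(sprintf(
          "linear_block: %s sections must be c(1, a1) or c(1, a1, a2)", what),
          call. = FALSE)
      }
    }
  }
  check_sections(num, "numerator"); check_sections(den, "denominator")
  blk <- structure(list(gain = as.numeric(gain),
                        num = lapply(num, as.numeric),
                        den = lapply(den, as.numeric)),
                   class = "linear_block")
  p <- lb_poles(blk)
  if (length(p) && max(Mod(p)) > 1 + tol) {
    stop(sprintf("linear_block: unstable pole |z| = %.6f > 1 + %g",
                 max(Mod(p)), tol), call. = FALSE)
  }
  blk
}

#' @export
print.linear_block <- function(x, ...) {
  fmt <- function(sec) {
    s <- "(1"
    for (i in 2:length(sec)) {
      s <- paste0(s, sprintf(" %+.4g z^-%d", sec[i], i - 1L))
    }
    paste0(s, ")")
  }
  num <- if (length(x$num)) paste(vapply(x$num, fmt, ""), collapse = "") else "1"
  den <- if (length(x$den)) paste(vapply(x$den, fmt, ""), collapse = "") else "1"
  cat(sprintf("<linear_block> H(z) = %.4g * %s / %s\n", x$gain, num, den))
  invisible(x)
}

# multiply factored sections into a single polynomial in z^-1
expand_sections <- function(sections) {
  out <- 1
  for (sec in sections) out <- conv_poly(out, sec)
  out
}

conv_poly <- function(a, b) {
  n <- length(a) + length(b) - 1L
  out <- numeric(n)
  for (i in seq_along(a)) {
    out[i:(i + length(b) - 1L)] <- out[i:(i + length(b) - 1L)] + a[i] * b
  }
  out
}

#' Expanded numerator/denominator coefficients of a linear block
#' @param block A [linear_block()].
#' @return List with `b` (numerator, including the gain) and `a`
#'   (denominator, leading coefficient 1), both in powers of `z^-1`.
#' @export
lb_coeffs <- function(block) {
  stopifnot(inherits(block, "linear_block"))
  list(b = block$gain * expand_sections(block$num),
       a = expand_sections(block$den))
}

#' Zeros and poles of a linear block
#' @param block A [linear_block()].
#' @return Complex vector of roots in the z plane.
#' @name lb_roots
#' @export
lb_zeros <- function(block) section_roots(block$num)

#' @rdname lb_roots
#' @export
lb_poles <- function(block) section_roots(block$den)

section_roots <- function(sections) {
  roots <- complex(0)
  for (sec in sections) {
    # section 1 + a1 z^-1 (+ a2 z^-2): roots in z of z^(d) + a1 z^(d-1) (+ a2)
    roots <- c(roots, polyroot(rev(sec)))
  }
  roots
}

# factor an expanded monic polynomial in z^-1 back into real sections
poly_to_sections <- function(coef) {
  coef <- coef / coef[1]
  d <- length(coef) - 1L
  if (d == 0L) return(list())
  r <- polyroot(rev(coef))
  secs <- list()
  used <- rep(FALSE, d)
  for (i in seq_len(d)) {
    if (used[i]) next
    if (abs(Im(r[i])) < 1e-9) {
      secs[[length(secs) + 1L]] <- c(1, -Re(r[i]))
      used[i] <- TRUE
    } else {
      j <- which(!used & abs(Im(r) + Im(r[i])) < 1e-7 &
                   abs(Re(r) - Re(r[i])) < 1e-7)
      j <- setdiff(j, i)[1]
      secs[[length(secs) + 1L]] <- c(1, -2 * Re(r[i]), Mod(r[i])^2)
      used[c(i, j)] <- TRUE
    }
  }
  secs
}

#' Build a linear block from expanded polynomial coefficients
#' @param b Numerator coefficients in powers of `z^-1` (b\[1\] is the gain).
#' @param a Denominator coefficients in powers of `z^-1`, `a[1] = 1`.
#' @param tol Pole-magnitude tolerance.
#' @return A [linear_block()] in factored form.
#' @export
lb_from_coeffs <- function(b, a, tol = 1e-6) {
  stopifnot(abs(a[1] - 1) < 1e-12, b[1] != 0)
  linear_block(gain = b[1], num = poly_to_sections(b), den = poly_to_sections(a),
               tol = tol)
}

#' Remove exactly cancelling numerator/denominator factors
#'
#' Published factored transfer functions sometimes carry a factor repeated in
#' numerator and denominator; this utility drops such pairs (coefficient-wise
#' agreement within `tol`) before filtering.
#'
#' @param block A [linear_block()].
#' @param tol Coefficient agreement tolerance.
#' @return The simplified `linear_block`.
#' @export
lb_simplify <- function(block, tol = 1e-12) {
  num <- block$num; den <- block$den
  i <- 1L
  while (i <= length(num)) {
    hit <- 0L
    for (j in seq_along(den)) {
      if (length(den[[j]]) == length(num[[i]]) &&
          all(abs(den[[j]] - num[[i]]) <= tol)) { hit <- j; break }
    }
    if (hit > 0L) {
      num[[i]] <- NULL; den[[hit]] <- NULL
    } else i <- i + 1L
  }
  linear_block(block$gain, num, den, tol = Inf)
}

#' Filter a sequence through a linear block
#'
#' Runs the causal difference equation
#' `a0 y\[t\] = sum b\[k\] u\[t-k\] - sum a\[k\] y\[t-k\]` with zero initial
#' state. Stability is enforced at construction, not here, so marginally
#' stable published fixtures can be simulated over finite horizons.
#'
#' @param block A [linear_block()].
#' @param u Numeric input sequence.
#' @return Numeric output sequence of the same length.
#' @export
lb_filter <- function(block, u) {
  ba <- lb_coeffs(block)
  as.numeric(signal::filter(ba$b, ba$a, as.numeric(u)))
}

#' The published example transfer functions
#'
#' The three z-domain linear blocks reported for the sagittal-moment (Mz)
#' output of the identified MISO Hammerstein-Wiener model, in their factored
#' printed form: `H1` drives the linear-acceleration input (gain -0.60),
#' `H2` the angular-velocity input (gain 0.11) and `H3` the generic
#' normalized Mz pattern (gain -0.50). Several denominator roots sit on the
#' unit circle (e.g. `1 - 1.97 z^-1 + 0.97 z^-2` has a root at `z = 1`), so
#' these blocks are marginally stable: they are intended for finite-horizon
#' simulation, not for refitting.
#'
#' @return Named list of three [linear_block()] objects `H1`, `H2`, `H3`.
#' @export
hw_fixture_blocks <- function() {
  list(
    H1 = linear_block(-0.60,
      num = list(c(1, -0.86), c(1, -0.86)),
      den = list(c(1, 0.83), c(1, 0.22), c(1, -0.09), c(1, -1.97, 0.97))),
    H2 = linear_block(0.11,
      num = list(c(1, -0.98), c(1, -1.99, 0.99), c(1, -1.83, 0.85)),
      den = list(c(1, -0.33), c(1, -0.15), c(1, -1.96, 0.98), c(1, -1.99, 1))),
    H3 = linear_block(-0.50,
      num = list(c(1, -1.99, 1.00)),
      den = list(c(1, -1.83, 0.85), c(1, -0.36), c(1, -1.99, 0.99),
                 c(1, 0.54, 0.63)))
  )
}
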