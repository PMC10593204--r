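# Polynomial and rational transfer-function algebra.
#
# Convention used throughout the package: polynomial coefficients are real,
# ordered in DESCENDING powers of s, and every transfer-function denominator
# is normalized monic after each operation.

poly_trim <- function(p) {
  nz <- which(abs(p) > 0)
  if (length(nz) == 0) return(0)
  p[nz[1]:length(p)]
}

poly_deg <- function(p) {
  p <- poly_trim(p)
  if (length(p) == 1 && p[1] == 0) return(-Inf)
  length(p) - 1L
}

poly_add <- function(a, b) {
  n <- max(length(a), length(b))
  poly_trim(c(numeric(n - length(a)), a) + c(numeric(n - length(b)), b))
}

# Direct (non-FFT) convolution: exact zeros stay exact, complex supported.
conv_direct <- function(a, b) {
  n <- length(a) + length(b) - 1L
  out <- if (is.complex(a) || is.complex(b)) complex(n) else numeric(n)
  for (i in seq_along(a)) {
    idx <- i:(i + length(b) - 1L)
    out[idx] <- out[idx] + a[i] * b
  }
  out
}

poly_mul <- function(a, b) {
  a <- poly_trim(a); b <- poly_trim(b)
  if ((length(a) == 1 && a == 0) || (length(b) == 1 && b == 0)) return(0)
  poly_trim(conv_direct(a, b))
}

poly_scale <- function(a, k) poly_trim(k * a)

# Horner evaluation; works for complex s.
poly_eval <- function(p, s) {
  acc <- rep(p[1] + 0i * s[1], length(s)) * 0 + p[1]
  if (length(p) > 1) for (i in 2:length(p)) acc <- acc * s + p[i]
  acc
}

poly_roots <- function(p) {
  p <- poly_trim(p)
  if (length(p) <= 1) return(complex(0))
  polyroot(rev(p))
}

poly_from_roots <- function(r, lead = 1) {
  p <- complex(real = 1)
  for (ri in r) p <- conv_direct(p, c(1 + 0i, -ri))
  poly_trim(Re(p) * lead)
}

# Exact polynomial division a / b, asserting the remainder is negligible.
poly_div_exact <- function(a, b, tol = 1e-9) {
  a <- poly_trim(a); b <- poly_trim(b)
  na <- length(a); nb <- length(b)
  if (na < nb) stop("degree of dividend below divisor", call. = FALSE)
  q <- numeric(na - nb + 1)
  r <- a
  for (i in seq_along(q)) {
    q[i] <- r[i] / b[1]
    r[i:(i + nb - 1)] <- r[i:(i + nb - 1)] - q[i] * b
  }
  rem <- r[(na - nb + 2):na]
  if (max(abs(rem)) > tol * max(1, max(abs(a)))) {
    stop("polynomial division has nonzero remainder", call. = FALSE)
  }
  poly_trim(q)
}

#' Rational transfer function in the Laplace variable
#'
#' Constructs a continuous-time single-input single-output transfer function
#' `num(s)/den(s)`. Coefficients are given in descending powers of `s`; the
#' denominator is normalized monic (leading coefficient 1) and the numerator
#' rescaled accordingly, so two representations of the same transfer function
#' have identical coefficient vectors after [tf_minreal()].
#'
#' @param num Numeric vector of numerator coefficients, descending powers of s.
#' @param den Numeric vector of denominator coefficients, descending powers of
#'   s. Must not be the zero polynomial.
#' @return An object of class `"tf"`: a list with elements `num` and `den`.
#' @examples
#' P <- tf(28.57 / 70.56, c(1, 1 / 70.56)) # first-order heart-rate plant
#' tf_dcgain(P)
#' @export
tf <- function(num, den) {
  num <- poly_trim(as.numeric(num))
  den <- poly_trim(as.numeric(den))
  if (length(den) == 1 && den[1] == 0) stop("zero denominator", call. = FALSE)
  num <- num / den[1]
  den <- den / den[1]
  structure(list(num = num, den = den), class = "tf")
}

as_tf <- function(x) {
  if (inherits(x, "tf")) return(x)
  if (is.numeric(x) && length(x) == 1) return(tf(x, 1))
  stop("cannot coerce to tf", call. = FALSE)
}

#' @export
print.tf <- function(x, ...) {
  fmt <- function(p) paste(signif(p, 6), collapse = " ")
  cat("Transfer function (coefficients in descending powers of s)\n")
  cat("  num:", fmt(x$num), "\n")
  cat("  den:", fmt(x$den), "\n")
  invisible(x)
}

#' Degree bookkeeping for transfer functions
#'
#' The relative degree is `deg(den) - deg(num)`; a transfer function is proper
#' when it is >= 0 and strictly proper when it is >= 1 (low-pass roll-off).
#'
#' @param x A [tf()] object.
#' @return `tf_rel_degree()` an integer; the predicates a logical scalar.
#' @export
tf_rel_degree <- function(x) poly_deg(x$den) - poly_deg(x$num)

#' @rdname tf_rel_degree
#' @export
tf_is_proper <- function(x) tf_rel_degree(x) >= 0

#' @rdname tf_rel_degree
#' @export
tf_is_strictly_proper <- function(x) tf_rel_degree(x) >= 1

#' Transfer function arithmetic
#'
#' Addition, multiplication and inversion on [tf()] objects. Sums are formed
#' over the common denominator and products multiply numerators and
#' denominators; common factors are never cancelled silently — cancellation is
#' an explicit step via [tf_minreal()].
#'
#' @param a,b [tf()] objects (or scalars, coerced).
#' @return A [tf()] object.
#' @export
tf_add <- function(a, b) {
  a <- as_tf(a); b <- as_tf(b)
  tf(poly_add(poly_mul(a$num, b$den), poly_mul(b$num, a$den)),
     poly_mul(a$den, b$den))
}

#' @rdname tf_add
#' @export
tf_mul <- function(a, b) {
  a <- as_tf(a); b <- as_tf(b)
  tf(poly_mul(a$num, b$num), poly_mul(a$den, b$den))
}

#' @rdname tf_add
#' @export
tf_inverse <- function(a) {
  a <- as_tf(a)
  if (length(a$num) == 1 && a$num[1] == 0) stop("cannot invert zero", call. = FALSE)
  tf(a$den, a$num)
}

#' @export
Ops.tf <- function(e1, e2) {
  if (nargs() == 1) {
    if (.Generic == "-") return(tf_mul(as_tf(e1), tf(-1, 1)))
    stop("unsupported unary operator for tf", call. = FALSE)
  }
  e1 <- as_tf(e1); e2 <- as_tf(e2)
  switch(.Generic,
    "+" = tf_add(e1, e2),
    "-" = tf_add(e1, tf_mul(e2, tf(-1, 1))),
    "*" = tf_mul(e1, e2),
    "/" = tf_mul(e1, tf_inverse(e2)),
    stop("unsupported operator for tf", call. = FALSE)
  )
}

#' Minimal realization by pole-zero cancellation
#'
#' Cancels numerator and denominator roots that agree within a relative
#' tolerance scaled by root magnitude, then re-normalizes the denominator
#' monic. The pole-cancelling compensator synthesis creates exact common
#' factors, but numerical root finders split repeated roots by about the
#' square root of machine precision, so the pairing tolerance cannot be
#' tighter than that; every reduction is verified by cross-multiplication
#' against the original fraction and reverted if it fails, so a cancellation
#' is never accepted on root proximity alone.
#'
#' @param a A [tf()] object.
#' @param tol Relative tolerance on root distance (scaled by `max(1, |root|)`).
#' @return A [tf()] object with common factors removed.
#' @export
tf_minreal <- function(a, tol = 1e-6) {
  stopifnot(tol > 0)
  a <- as_tf(a)
  if (length(a$num) == 1 && a$num[1] == 0) return(tf(0, 1))
  # constant multiples reduce exactly, whatever the (possibly repeated) roots
  if (length(a$num) == length(a$den)) {
    k <- poly_trim(a$num)[1]
    if (max(abs(a$num - k * a$den)) <= 1e-10 * max(abs(a$num))) {
      return(tf(k, 1))
    }
  }
  zn <- poly_roots(a$num)
  zd <- poly_roots(a$den)
  lead_num <- poly_trim(a$num)[1]
  keep_d <- rep(TRUE, length(zd))
  for (i in seq_along(zn)) {
    if (length(zd) == 0) break
    cand <- which(keep_d)
    if (length(cand) == 0) break
    dist <- abs(zd[cand] - zn[i])
    j <- cand[which.min(dist)]
    if (min(dist) <= tol * max(1, abs(zn[i]))) {
      keep_d[j] <- FALSE
      zn[i] <- NA_complex_
    }
  }
  if (!anyNA(zn)) return(a)
  red <- tf(poly_from_roots(zn[!is.na(zn)], lead_num),
            poly_from_roots(zd[keep_d], 1))
  # verify num_red * den == den_red * num before accepting the reduction
  lhs <- poly_mul(red$num, a$den)
  rhs <- poly_mul(red$den, a$num)
  scale <- max(abs(rhs), abs(lhs))
  err <- max(abs(poly_add(lhs, poly_scale(rhs, -1)))) / scale
  if (err > 1e-5) a else red
}

#' Steady-state (DC) gain
#'
#' @param x A [tf()] object.
#' @return `num(0)/den(0)`.
#' @export
tf_dcgain <- function(x) {
  as.numeric(Re(poly_eval(x$num, 0 + 0i) / poly_eval(x$den, 0 + 0i)))
}

#' Frequency response
#'
#' Evaluates a transfer function along the imaginary axis at `s = j 2 pi f`.
#'
#' @param x A [tf()] object.
#' @param freqs_hz Vector of strictly positive frequencies in Hz.
#' @return Complex vector of gains, one per frequency.
#' @examples
#' mag_db(freq_response(tf(1, c(70.56, 1)), 1 / (2 * pi * 70.56)))  # -3.01 dB
#' @export
freq_response <- function(x, freqs_hz) {
  stopifnot(all(freqs_hz > 0))
  s <- 2i * pi * freqs_hz
  den_v <- poly_eval(x$den, s)
  if (any(Mod(den_v) < 1e-290)) {
    stop("frequency response evaluated at a pole on the imaginary axis",
         call. = FALSE)
  }
  poly_eval(x$num, s) / den_v
}

#' @rdname freq_response
#' @param g Complex (or numeric) gain values.
#' @export
mag_db <- function(g) 20 * log10(Mod(g))

#' Hurwitz stability test
#'
#' @param p Numeric coefficient vector (descending powers of s), not all zero.
#' @return `TRUE` iff every root has strictly negative real part.
#' @export
is_hurwitz <- function(p) {
  p <- poly_trim(p)
  if (length(p) == 1 && p[1] == 0) stop("zero polynomial", call. = FALSE)
  r <- poly_roots(p)
  length(r) == 0 || all(Re(r) < 0)
}

tf_is_stable <- function(x) is_hurwitz(x$den)

# Controllable canonical state-space realization of a proper tf.
tf_to_ss <- function(x) {
  if (!tf_is_proper(x)) stop("transfer function is not proper", call. = FALSE)
  den <- x$den
  n <- length(den) - 1L
  num <- c(numeric(length(den) - length(x$num)), x$num)
  D <- num[1]
  rem <- poly_trim(num[-1] - D * den[-1])
  if (n == 0) {
    return(list(A = matrix(0, 0, 0), B = matrix(0, 0, 1),
                C = matrix(0, 1, 0), D = D, n = 0L))
  }
  A <- rbind(-den[-1], cbind(diag(1, n - 1, n - 1), numeric(n - 1)))
  B <- matrix(c(1, numeric(n - 1)), ncol = 1)
  C <- matrix(c(numeric(n - length(rem)), rem), nrow = 1)
  list(A = A, B = B, C = C, D = D, n = as.integer(n))
}

# Exact zero-order-hold discretization of a state-space model.
ss_zoh <- function(ss, Ts) {
  n <- ss$n
  if (n == 0) return(list(Ad = ss$A, Bd = matrix(0, 0, 1), C = ss$C, D = ss$D, n = 0L))
  M <- rbind(cbind(ss$A, ss$B), matrix(0, 1, n + 1))
  E <- as.matrix(Matrix::expm(M * Ts))
  list(Ad = E[seq_len(n), seq_len(n), drop = FALSE],
       Bd = E[seq_len(n), n + 1, drop = FALSE],
       C = ss$C, D = ss$D, n = n)
}

# Unit-step value at a single time, exact via augmented matrix exponential.
step_value <- function(ss, t) {
  if (ss$n == 0) return(ss$D)
  n <- ss$n
  M <- rbind(cbind(ss$A, ss$B), matrix(0, 1, n + 1))
  E <- as.matrix(Matrix::expm(M * t))
  as.numeric(ss$C %*% E[seq_len(n), n + 1, drop = FALSE] + ss$D)
}

#' Unit-step response
#'
#' Computes the unit-step response by exact zero-order-hold discretization of a
#' controllable canonical state-space realization (uniform grids) or by direct
#' matrix-exponential evaluation (arbitrary grids); no approximate integration
#' is involved, which matters because the heart-rate time constants (18-70 s)
#' are probed at 1 s resolution.
#'
#' @param x A proper [tf()] object.
#' @param t_grid Non-negative, strictly increasing times in seconds.
#' @return A [tibble::tibble()] with columns `t` and `y`.
#' @examples
#' step_response(tf(1, c(70.56, 1)), c(0, 70.56))  # reaches 1 - exp(-1)
#' @export
step_response <- function(x, t_grid) {
  if (!tf_is_proper(x)) stop("transfer function is not proper", call. = FALSE)
  stopifnot(all(t_grid >= 0), all(diff(t_grid) > 0) || length(t_grid) == 1)
  ss <- tf_to_ss(x)
  dt <- diff(t_grid)
  uniform <- length(dt) > 0 && diff(range(dt)) <= 1e-9 * max(dt)
  if (uniform && abs(t_grid[1]) < 1e-12 && ss$n > 0) {
    d <- ss_zoh(ss, dt[1])
    y <- numeric(length(t_grid))
    xs <- matrix(0, ss$n, 1)
    y[1] <- ss$D
    for (k in 2:length(t_grid)) {
      xs <- d$Ad %*% xs + d$Bd
      y[k] <- as.numeric(d$C %*% xs + d$D)
    }
  } else {
    y <- vapply(t_grid, function(ti) step_value(ss, ti), numeric(1))
  }
  tibble::tibble(t = t_grid, y = y)
}

#' 10-90% rise time of the step response
#'
#' Time for the unit-step response to travel from 10% to 90% of its final
#' value, with the crossings located by root bisection to about 1e-6 s
#' relative accuracy. Intended for stable transfer functions with monotone
#' step response (the critically damped targets used here).
#'
#' @param x A proper, stable [tf()] object with nonzero DC gain.
#' @return Rise time in seconds.
#' @examples
#' rise_time_10_90(tf(1, c(70.56, 1)))  # 70.56 * log(9)
#' @export
rise_time_10_90 <- function(x) {
  if (!tf_is_proper(x)) stop("transfer function is not proper", call. = FALSE)
  if (!tf_is_stable(x)) stop("unstable transfer function", call. = FALSE)
  final <- tf_dcgain(x)
  if (abs(final) < 1e-300) stop("zero final value", call. = FALSE)
  ss <- tf_to_ss(x)
  if (ss$n == 0) stop("degenerate (instantaneous) step response", call. = FALSE)
  slowest <- 1 / min(abs(Re(poly_roots(x$den))))
  t_max <- 60 * slowest
  cross <- function(frac) {
    f <- function(t) step_value(ss, t) / final - frac
    t_hi <- slowest
    while (f(t_hi) < 0 && t_hi < t_max) t_hi <- t_hi * 2
    if (f(t_hi) < 0) stop("step response does not reach final value", call. = FALSE)
    uniroot(f, c(0, t_hi), tol = 1e-7 * slowest)$root
  }
  cross(0.9) - cross(0.1)
}
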