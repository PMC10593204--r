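# Constant input-sensitivity compensator synthesis.
#
# For a stable, strictly proper plant P = B/A (A monic) the feedback
# compensator C = g0' A / (s H') with g0' = A(0)/B(0) and H' = (A - g0' B)/s
# places the whole closed-loop characteristic polynomial at A^2 and makes the
# input sensitivity U = C/(1 + C P) exactly the constant g0' at every
# frequency. S = s H'/A and T = g0' B / A follow by cancellation.

#' Heart-rate plant models
#'
#' Deviation models of the heart-rate response (bpm) to treadmill speed (m/s).
#' The first-order form `k1 / (tau1 s + 1)` lumps the fast (Phase I) and slow
#' (Phase II) components of the cardiac response into one time constant; the
#' two-phase form `k2 / ((tau21 s + 1)(tau22 s + 1))` keeps a separate time
#' constant per phase (convention `tau21 <= tau22`, fast phase first).
#'
#' @param k Steady-state gain, bpm per m/s; positive.
#' @param tau,tau_fast,tau_slow Time constants in seconds; positive.
#' @return A [tf()] object with attributes `order` and `params`.
#' @examples
#' first_order_plant(28.57, 70.56)
#' second_order_plant(24.70, 18.60, 37.95)
#' @export
first_order_plant <- function(k, tau) {
  stopifnot(k > 0, tau > 0)
  p <- tf(k / tau, c(1, 1 / tau))
  attr(p, "order") <- 1L
  attr(p, "params") <- list(k = k, tau = tau)
  p
}

#' @rdname first_order_plant
#' @export
second_order_plant <- function(k, tau_fast, tau_slow) {
  stopifnot(k > 0, tau_fast > 0, tau_slow > 0)
  if (tau_fast > tau_slow) stop("tau_fast must not exceed tau_slow", call. = FALSE)
  den <- poly_mul(c(1, 1 / tau_fast), c(1, 1 / tau_slow))
  p <- tf(k / (tau_fast * tau_slow), den)
  attr(p, "order") <- 2L
  attr(p, "params") <- list(k = k, tau_fast = tau_fast, tau_slow = tau_slow)
  p
}

#' Nominal treadmill heart-rate plant parameters
#'
#' Average identified model parameters used to compute the deployed
#' compensators: `k1 = 28.57` bpm/(m/s), `tau1 = 70.56` s for the first-order
#' model and `k2 = 24.70` bpm/(m/s), `tau21 = 18.60` s, `tau22 = 37.95` s for
#' the two-phase model.
#'
#' @param order 1 or 2.
#' @return A [tf()] plant, as from [first_order_plant()] / [second_order_plant()].
#' @export
nominal_plant <- function(order = 2) {
  if (order == 1) first_order_plant(28.57, 70.56)
  else if (order == 2) second_order_plant(24.70, 18.60, 37.95)
  else stop("order must be 1 or 2", call. = FALSE)
}

new_compensator_design <- function(plant, g0_prime, H_prime, C, S, T, label = NULL) {
  structure(
    list(plant = plant, g0_prime = g0_prime, H_prime = H_prime,
         C = C, S = S, T = T, U_const = g0_prime, label = label),
    class = "compensator_design")
}

#' @export
print.compensator_design <- function(x, ...) {
  cat("Constant input-sensitivity compensator design\n")
  cat(sprintf("  U = g0' = %.3g (m/s)/bpm  (%.2f dB at all frequencies)\n",
              x$g0_prime, 20 * log10(abs(x$g0_prime))))
  cat("  C(s): num", paste(signif(x$C$num, 3), collapse = " "),
      "| den", paste(signif(x$C$den, 3), collapse = " "), "\n")
  invisible(x)
}

#' Synthesize the constant input-sensitivity compensator
#'
#' Given a stable, strictly proper plant `P = B/A` (A monic), returns the
#' unique integral-action compensator `C = g0' A / (s H')` for which the input
#' sensitivity function is the constant `g0' = A(0)/B(0)` at every frequency.
#' All closed-loop poles are placed at the open-loop poles, so the closed-loop
#' characteristic polynomial equals `A^2`; `H'` is obtained by the exact
#' polynomial division `(A - g0' B)/s`, whose remainder vanishes by
#' construction of `g0'`.
#'
#' @param plant A strictly proper, stable [tf()] plant with `B(0) != 0`.
#' @return A `compensator_design` object with elements `g0_prime`, `H_prime`,
#'   `C`, `S`, `T`, `U_const`.
#' @examples
#' d <- synthesize_constant_U(nominal_plant(2))
#' signif(d$C$num, 3) # 0.0405 0.00324 0.0000574
#' @export
synthesize_constant_U <- function(plant) {
  plant <- as_tf(plant)
  if (!tf_is_strictly_proper(plant)) {
    stop("plant must be strictly proper", call. = FALSE)
  }
  A <- plant$den
  B <- plant$num
  if (!is_hurwitz(A)) {
    stop("unstable plant, cancellation design invalid", call. = FALSE)
  }
  B0 <- poly_eval(B, 0)
  if (abs(B0) < 1e-300) stop("plant zero at origin, g0' undefined", call. = FALSE)
  g0 <- as.numeric(Re(poly_eval(A, 0) / B0))
  H_prime <- poly_div_exact(poly_add(A, poly_scale(B, -g0)), c(1, 0))
  if (!is_hurwitz(H_prime)) {
    warning("H' is not Hurwitz: compensator has unstable pole", call. = FALSE)
  }
  C <- tf(poly_scale(A, g0), poly_mul(c(1, 0), H_prime))
  S <- tf(poly_mul(c(1, 0), H_prime), A)
  T <- tf(poly_scale(B, g0), A)
  new_compensator_design(plant, g0, H_prime, C, S, T)
}

#' Closed-form designs for the first-order and two-phase plants
#'
#' Specializations of [synthesize_constant_U()]: for the first-order plant
#' `C = (1/k)(s + 1/tau)/s`; for the two-phase plant
#' `C = (1/k)(s^2 + (1/tau21 + 1/tau22) s + 1/(tau21 tau22)) / (s (s + 1/tau21 + 1/tau22))`.
#' They agree coefficient-wise with the general synthesis and exist mainly as
#' its independent cross-check.
#'
#' @param k,tau,tau_fast,tau_slow Plant parameters as in [first_order_plant()].
#' @return A `compensator_design` object.
#' @export
closed_form_first_order <- function(k, tau) {
  stopifnot(k > 0, tau > 0)
  g0 <- 1 / k
  plant <- first_order_plant(k, tau)
  C <- tf(c(g0, g0 / tau), c(1, 0))
  S <- tf(c(1, 0), c(1, 1 / tau))
  T <- tf(1 / tau, c(1, 1 / tau))
  new_compensator_design(plant, g0, 1, C, S, T)
}

#' @rdname closed_form_first_order
#' @export
closed_form_second_order <- function(k, tau_fast, tau_slow) {
  stopifnot(k > 0, tau_fast > 0, tau_slow > 0)
  g0 <- 1 / k
  h0 <- 1 / tau_fast + 1 / tau_slow
  plant <- second_order_plant(k, tau_fast, tau_slow)
  A <- plant$den
  C <- tf(poly_scale(A, g0), c(1, h0, 0))
  S <- tf(c(1, h0, 0), A)
  T <- tf(1 / (tau_fast * tau_slow), A)
  new_compensator_design(plant, g0, c(1, h0), C, S, T)
}

#' Classical sensitivity functions of a feedback loop
#'
#' For plant `P` and compensator `C` in a unit-feedback loop, returns the
#' sensitivity `S = 1/(1 + CP)` (disturbance to output), complementary
#' sensitivity `T = CP/(1 + CP)` (reference to output) and input sensitivity
#' `U = C/(1 + CP)` (disturbance to control signal), each after
#' [tf_minreal()]. This is the generic oracle against which the pole-cancelled
#' closed forms are verified.
#'
#' @param P,C [tf()] objects.
#' @param tol Cancellation tolerance passed to [tf_minreal()].
#' @return A list with elements `S`, `T`, `U`.
#' @export
generic_sensitivities <- function(P, C, tol = 1e-6) {
  P <- as_tf(P); C <- as_tf(C)
  L <- tf_mul(C, P)
  one_plus_L <- tf_add(tf(1, 1), L)
  if (length(poly_trim(one_plus_L$num)) == 1 &&
      poly_trim(one_plus_L$num)[1] == 0) {
    stop("algebraic loop: 1 + CP is identically zero", call. = FALSE)
  }
  inv <- tf_inverse(one_plus_L)
  list(S = tf_minreal(inv, tol),
       T = tf_minreal(tf_mul(L, inv), tol),
       U = tf_minreal(tf_mul(C, inv), tol))
}

#' Critically damped closed-loop target response
#'
#' Returns `T_cl(s) = p^2/(s + p)^2` — unit DC gain, a critically damped
#' double real pole — with `p` chosen so the 10-90% step rise time equals
#' `rise_time` seconds. By time scaling, `p = c / rise_time` where `c` is the
#' 10-90% width of the unit-pole response `1 - (1 + t) e^{-t}`.
#'
#' @param rise_time Target 10-90% rise time in seconds; positive.
#' @return A [tf()] object.
#' @examples
#' design_Tcl(150) # double pole near 0.02239 rad/s
#' @export
design_Tcl <- function(rise_time) {
  stopifnot(rise_time > 0)
  crossing <- function(frac) {
    uniroot(function(t) 1 - (1 + t) * exp(-t) - frac, c(1e-9, 60),
            tol = 1e-12)$root
  }
  c_unit <- crossing(0.9) - crossing(0.1)
  p <- c_unit / rise_time
  tf(p^2, poly_mul(c(1, p), c(1, p)))
}

new_prefilter_design <- function(T_cl, C_pf, rise_time_target = NA_real_) {
  structure(list(T_cl = T_cl, C_pf = C_pf, rise_time_target = rise_time_target),
            class = "prefilter_design")
}

#' @export
print.prefilter_design <- function(x, ...) {
  cat("Reference prefilter design\n")
  cat("  C_pf num:", paste(signif(x$C_pf$num, 3), collapse = " "),
      "| den:", paste(signif(x$C_pf$den, 3), collapse = " "), "\n")
  invisible(x)
}

#' Reference prefilter shaping the overall tracking response
#'
#' Designs `C_pf = T_o^{-1} T_cl` so that the reference-to-output transfer of
#' the two-degree-of-freedom loop equals the prescribed `T_cl`. Requires a
#' minimum-phase `T_o` (no zeros in the closed right half-plane) and
#' `T_cl` rolling off at least as fast as `T_o` so the prefilter is proper.
#'
#' @param T_o Nominal complementary sensitivity, a [tf()].
#' @param T_cl Target closed-loop transfer, a [tf()].
#' @return A `prefilter_design` with elements `T_cl` and `C_pf`.
#' @export
design_prefilter <- function(T_o, T_cl) {
  T_o <- as_tf(T_o); T_cl <- as_tf(T_cl)
  z <- poly_roots(T_o$num)
  if (any(Re(z) >= -1e-12)) {
    stop("unstable prefilter: T_o has zeros in the closed right half-plane",
         call. = FALSE)
  }
  if (abs(tf_dcgain(T_o)) < 1e-300) stop("T_o has zero DC gain", call. = FALSE)
  C_pf <- tf_minreal(tf_mul(tf_inverse(T_o), T_cl))
  if (!tf_is_proper(C_pf)) {
    stop("T_cl rolls off slower than T_o: prefilter improper", call. = FALSE)
  }
  new_prefilter_design(T_cl, C_pf)
}

#' Heart-rate-variability band edges
#'
#' The four conventional HRV analysis band boundaries: ultra-low frequency up
#' to 1/300 Hz, very-low to 0.04 Hz, low to 0.15 Hz and high to 0.4 Hz.
#'
#' @return Named numeric vector of four frequencies in Hz, strictly increasing.
#' @export
hrv_band_edges <- function() {
  c(ulf_vlf = 1 / 300, vlf_lf = 0.04, lf_hf = 0.15, hf_upper = 0.4)
}

#' Frequency-response table of a design's sensitivity functions
#'
#' Magnitudes (dB) of the input sensitivity `U`, sensitivity `S` and
#' complementary sensitivity `T` of a design over a log-spaced grid, with HRV
#' band edges flagged.
#'
#' @param design A `compensator_design`.
#' @param freqs_hz Frequencies in Hz (default log grid 1e-4 to 1 Hz).
#' @param n Number of grid points when `freqs_hz` is not supplied.
#' @return A tibble with columns `freq_hz`, `U_db`, `S_db`, `T_db`, `band_edge`.
#' @export
bode_table <- function(design, freqs_hz = NULL, n = 200) {
  if (is.null(freqs_hz)) {
    freqs_hz <- sort(unique(c(10^seq(-4, 0, length.out = n), hrv_band_edges())))
  }
  tibble::tibble(
    freq_hz = freqs_hz,
    U_db = mag_db(freq_response(design$C, freqs_hz) /
                    (1 + freq_response(tf_mul(design$C, design$plant), freqs_hz))),
    S_db = mag_db(freq_response(design$S, freqs_hz)),
    T_db = mag_db(freq_response(design$T, freqs_hz)),
    band_edge = vapply(freqs_hz, function(f)
      any(abs(f - hrv_band_edges()) < 1e-12), logical(1))
  )
}
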