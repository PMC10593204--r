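# Closed-loop treadmill session simulator.
#
# Inner loop at 1 Hz (heart-rate sampling); the compensator and reference
# prefilter run at 0.2 Hz (5 s interval) on the 5-sample average of the
# measured heart rate. The plant is advanced by exact zero-order-hold
# discretization, which is exact because the commanded speed is piecewise
# constant over each control interval.

#' Exercise protocol specification
#'
#' Timing of one feedback-control test: a 35-minute formal measurement phase
#' sampled at 1 Hz with the compensator running every `control_Ts` seconds,
#' and the outcome evaluation window `[eval_start_s, eval_end_s]` on the
#' control-rate grid. Defaults follow the study protocol (warm-up 600 s and
#' rest 600 s are recorded for completeness; the simulator starts the
#' measurement phase from rest equilibrium, and the evaluation window lies
#' well inside the measurement phase).
#'
#' @param warmup_s,rest_s,measurement_s Phase durations in seconds.
#' @param eval_start_s,eval_end_s Evaluation window bounds in seconds
#'   (inclusive), on the control-rate grid.
#' @param control_Ts Compensator sample interval in seconds.
#' @param hr_sample_hz Heart-rate sampling rate in Hz.
#' @param target_hr_bpm Target heart rate in bpm (NA: derived from age via
#'   [target_hr()]).
#' @return A list of class `protocol_spec`.
#' @export
protocol_spec <- function(warmup_s = 600, rest_s = 600, measurement_s = 2100,
                          eval_start_s = 295, eval_end_s = 2095,
                          control_Ts = 5, hr_sample_hz = 1,
                          target_hr_bpm = NA_real_) {
  stopifnot(measurement_s > 0, control_Ts > 0, hr_sample_hz > 0)
  if (abs(control_Ts * hr_sample_hz - round(control_Ts * hr_sample_hz)) > 1e-9) {
    stop("control_Ts must be a whole number of heart-rate samples", call. = FALSE)
  }
  if (eval_start_s < 0 || eval_end_s > measurement_s || eval_start_s > eval_end_s) {
    stop("evaluation window must lie inside the measurement phase", call. = FALSE)
  }
  structure(list(warmup_s = warmup_s, rest_s = rest_s,
                 measurement_s = measurement_s,
                 eval_start_s = eval_start_s, eval_end_s = eval_end_s,
                 control_Ts = control_Ts, hr_sample_hz = hr_sample_hz,
                 target_hr_bpm = target_hr_bpm),
            class = "protocol_spec")
}

#' Mid-level target heart rate from age
#'
#' The prediction equation `HR_m = 0.765 (220 - age)` bpm, placing intensity
#' at the border between moderate and vigorous.
#'
#' @param age Age in years, in (0, 220).
#' @return Target heart rate in bpm.
#' @examples
#' target_hr(30) # 145.35
#' @export
target_hr <- function(age) {
  stopifnot(all(age > 0), all(age < 220))
  0.765 * (220 - age)
}

#' Bilinear (Tustin) discretization of a continuous transfer function
#'
#' Maps `s <- (2/Ts)(z - 1)/(z + 1)`. The trapezoidal rule sends the
#' integrator pole at `s = 0` exactly to `z = 1`, preserving integral action,
#' and matches the continuous frequency response closely in the sub-0.4 Hz
#' bands where the heart-rate loop lives.
#'
#' @param c A proper [tf()] object.
#' @param Ts Sample interval in seconds.
#' @return A list of class `discrete_filter` with direct-form coefficient
#'   vectors `b` (input) and `a` (output, `a[1] == 1`) in descending powers of
#'   z, and `Ts`.
#' @export
discretize_tustin <- function(c, Ts) {
  c <- as_tf(c)
  if (!tf_is_proper(c)) stop("transfer function must be proper", call. = FALSE)
  stopifnot(Ts > 0)
  n <- poly_deg(c$den)
  num <- c(numeric(n + 1 - length(c$num)), c$num)
  den <- c$den
  k <- 2 / Ts
  zm1 <- c(1, -1); zp1 <- c(1, 1)
  term <- function(coef_vec) {
    acc <- 0
    for (j in 0:n) {
      # coefficient of s^(n-j) multiplied through by (z+1)^n
      pz <- 1
      m <- n - j
      if (m > 0) for (i in seq_len(m)) pz <- conv_direct(pz, zm1)
      if (j > 0) for (i in seq_len(j)) pz <- conv_direct(pz, zp1)
      acc <- poly_add(acc, poly_scale(pz, coef_vec[j + 1] * k^m))
    }
    acc
  }
  b <- term(num); a <- term(den)
  b <- c(numeric(n + 1 - length(b)), b)
  a <- c(numeric(n + 1 - length(a)), a)
  b <- b / a[1]; a <- a / a[1]
  structure(list(b = b, a = a, Ts = Ts), class = "discrete_filter")
}

# Evaluate a discrete filter's frequency response at z = exp(j 2 pi f Ts).
discrete_freq_response <- function(filt, freqs_hz) {
  z <- exp(2i * pi * freqs_hz * filt$Ts)
  poly_eval(filt$b, z) / poly_eval(filt$a, z)
}

# One direct-form step of a discrete filter. State is a list of input and
# output histories (most recent first).
filter_init <- function(filt) {
  n <- length(filt$a) - 1L
  list(x = numeric(max(n, length(filt$b) - 1L)), y = numeric(n))
}

filter_step <- function(filt, state, x_new, y_override = NULL) {
  bx <- filt$b[1] * x_new
  if (length(state$x) > 0) {
    bx <- bx + sum(filt$b[-1] * state$x[seq_len(length(filt$b) - 1L)])
  }
  ay <- if (length(state$y) > 0) sum(filt$a[-1] * state$y) else 0
  y <- bx - ay
  y_store <- if (is.null(y_override)) y else y_override
  if (length(state$x) > 0) state$x <- c(x_new, head(state$x, -1))
  if (length(state$y) > 0) state$y <- c(y_store, head(state$y, -1))
  list(state = state, y = y)
}

#' Synthetic heart-rate-variability-like disturbance
#'
#' Zero-mean Gaussian white noise shaped by a one-pole low-pass filter at the
#' given cutoff and scaled so the stationary process standard deviation equals
#' `sd` bpm. The filter state is initialized from the stationary distribution,
#' so the series is stationary from the first sample and fully reproducible
#' from the seed.
#'
#' @param n_samples Number of samples; positive.
#' @param fs Sampling rate in Hz.
#' @param sd Target standard deviation, bpm; non-negative.
#' @param cutoff_hz Low-pass cutoff, Hz; positive.
#' @param seed Integer seed.
#' @return Numeric vector of length `n_samples`, in bpm.
#' @export
gen_hrv_disturbance <- function(n_samples, fs = 1, sd = 2, cutoff_hz = 0.05,
                                seed = 1) {
  stopifnot(n_samples > 0, fs > 0, sd >= 0, cutoff_hz > 0)
  if (sd == 0) return(numeric(n_samples))
  alpha <- exp(-2 * pi * cutoff_hz / fs)
  old <- .Random.seed_safe()
  on.exit(.restore_seed(old), add = TRUE)
  set.seed(seed)
  w <- rnorm(n_samples)
  # stationary sd of y[k] = alpha y[k-1] + (1 - alpha) w[k] with unit-sd input
  stat_sd <- (1 - alpha) / sqrt(1 - alpha^2)
  init <- rnorm(1) * stat_sd
  y <- as.numeric(stats::filter((1 - alpha) * w, alpha,
                                method = "recursive", init = init))
  y * (sd / stat_sd)
}

.Random.seed_safe <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Simulate one closed-loop heart-rate control session
#'
#' Runs the measurement phase of the protocol: the plant (a deviation model
#' around `hr_rest`) is advanced at 1 Hz by exact zero-order-hold
#' discretization; the measured heart rate `z = y + n` is averaged over every
#' five consecutive samples; at each 5 s control instant the compensator
#' updates the commanded speed from the error between the filtered reference
#' and the averaged measurement, and the command is held (and clamped to
#' `[u_min, u_max]` with integration halted while saturated). The reference
#' path applies the prefiltered deviation step from `hr_rest` to the target.
#'
#' @param truth A one-row cohort tibble (see [sample_cohort()]) or a list with
#'   fields `k2`, `tau21`, `tau22`, `hr_rest`, `age`, `dist_sd`,
#'   `dist_cutoff_hz`, `noise_sd`, `seed`.
#' @param design A `compensator_design` (controller; designed from the nominal
#'   model, not from `truth`).
#' @param pf A `prefilter_design`.
#' @param proto A [protocol_spec()].
#' @param u_min,u_max Treadmill speed limits, m/s.
#' @param d,n Optional pre-generated disturbance and noise series at 1 Hz
#'   (used to share realizations across paired arms); defaults generated from
#'   `truth$seed`.
#' @return An object of class `hr_session`: list with `series` (1 Hz tibble:
#'   `t_s`, `hr_ref_bpm`, `hr_ref_filt_bpm`, `hr_true_bpm`, `hr_meas_bpm`,
#'   `hr_sim_bpm`, `speed_cmd_mps`, `disturbance_bpm`, `noise_bpm`), `control`
#'   (0.2 Hz tibble: `t_s`, `hr_ref_filt_bpm`, `hr_meas_avg_bpm`, `err_bpm`,
#'   `speed_cmd_mps`, `hr_sim_bpm`), and metadata.
#' @export
simulate_session <- function(truth, design, pf, proto = protocol_spec(),
                             u_min = 0.5, u_max = 6.0, d = NULL, n = NULL) {
  truth <- as.list(truth)
  Ts <- proto$control_Ts
  n_t <- as.integer(proto$measurement_s)          # samples at t = 0..n_t-1
  t_s <- seq(0, n_t - 1)
  target <- if (!is.na(proto$target_hr_bpm)) proto$target_hr_bpm else target_hr(truth$age)
  if (target <= truth$hr_rest) stop("target heart rate must exceed rest", call. = FALSE)
  dr <- target - truth$hr_rest                    # reference deviation step

  if (is.null(d)) d <- gen_hrv_disturbance(n_t, fs = proto$hr_sample_hz,
                                           sd = truth$dist_sd,
                                           cutoff_hz = truth$dist_cutoff_hz,
                                           seed = truth$seed)
  if (is.null(n)) {
    old <- .Random.seed_safe(); on.exit(.restore_seed(old), add = TRUE)
    set.seed(truth$seed + 1L)
    n <- if (truth$noise_sd > 0) rnorm(n_t, sd = truth$noise_sd) else numeric(n_t)
  }
  stopifnot(length(d) >= n_t, length(n) >= n_t)

  plant <- second_order_plant(truth$k2, truth$tau21, truth$tau22)
  pd <- ss_zoh(tf_to_ss(plant), 1 / proto$hr_sample_hz)
  ctrl <- discretize_tustin(design$C, Ts)
  ctrl_state <- filter_init(ctrl)
  # The reference path is feedforward with a constant target, so the filtered
  # reference is the exact continuous step response of C_pf sampled at the
  # control instants (no discretization error enters the reference).
  ctl_times <- seq(0, n_t - 1, by = Ts)
  rp_dev_ctl <- dr * step_response(pf$C_pf, ctl_times)$y

  # nominal simulated response: hr_rest + dr * unit step through T_cl
  hr_sim <- truth$hr_rest + dr * step_response(pf$T_cl, t_s)$y

  x <- matrix(0, pd$n, 1)
  y <- z <- u_held <- rp <- numeric(n_t)
  n_ctrl <- floor((n_t - 1) / Ts) + 1L
  ctl_t <- ctl_rp <- ctl_zbar <- ctl_e <- ctl_u <- numeric(n_ctrl)
  u_cur <- 0
  ci <- 0L
  for (k in seq_len(n_t)) {
    tk <- t_s[k]
    y[k] <- truth$hr_rest + as.numeric(pd$C %*% x) + d[k]
    if (abs(y[k]) > 300) stop("unstable simulation: |heart rate| exceeded 300 bpm",
                              call. = FALSE)
    z[k] <- y[k] + n[k]
    if (tk %% Ts == 0) {
      ci <- ci + 1L
      rp_dev <- rp_dev_ctl[ci]
      zbar <- mean(z[max(1, k - Ts + 1):k])
      e <- (truth$hr_rest + rp_dev) - zbar
      stc <- filter_step(ctrl, ctrl_state, e)
      u_raw <- stc$y
      u_cur <- min(max(u_raw, u_min), u_max)
      # write the clamped command back into the recursion history so the
      # integral action does not wind up while saturated
      ctrl_state <- stc$state
      if (length(ctrl_state$y) > 0) ctrl_state$y[1] <- u_cur
      ctl_t[ci] <- tk; ctl_rp[ci] <- truth$hr_rest + rp_dev
      ctl_zbar[ci] <- zbar; ctl_e[ci] <- e; ctl_u[ci] <- u_cur
    }
    rp[k] <- truth$hr_rest + if (ci > 0) ctl_rp[ci] - truth$hr_rest else 0
    u_held[k] <- u_cur
    x <- pd$Ad %*% x + pd$Bd * u_cur
  }

  series <- tibble::tibble(
    t_s = t_s, hr_ref_bpm = target, hr_ref_filt_bpm = rp,
    hr_true_bpm = y, hr_meas_bpm = z, hr_sim_bpm = hr_sim,
    speed_cmd_mps = u_held, disturbance_bpm = d[seq_len(n_t)],
    noise_bpm = n[seq_len(n_t)])
  hr_sim_ctl <- hr_sim[match(ctl_t, t_s)]
  control <- tibble::tibble(
    t_s = ctl_t, hr_ref_filt_bpm = ctl_rp, hr_meas_avg_bpm = ctl_zbar,
    err_bpm = ctl_e, speed_cmd_mps = ctl_u, hr_sim_bpm = hr_sim_ctl)
  structure(list(series = series, control = control, proto = proto,
                 target_hr_bpm = target, hr_rest_bpm = truth$hr_rest,
                 u_min = u_min, u_max = u_max, truth = truth),
            class = "hr_session")
}

#' @export
print.hr_session <- function(x, ...) {
  cat(sprintf("Closed-loop heart-rate session: %d s at %g Hz, target %.1f bpm\n",
              nrow(x$series), x$proto$hr_sample_hz, x$target_hr_bpm))
  o <- session_outcomes(x)
  cat(sprintf("  evaluation window RMSE %.3f bpm, P_grad_u %.3g m^2/s^2 (N = %d)\n",
              o$rmse_bpm, o$p_grad_u_m2s2, o$n_samples))
  invisible(x)
}
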