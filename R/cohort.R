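# Synthetic participants and the paired in-silico experiment.

#' Sample a synthetic participant cohort
#'
#' Each participant's "true" speed-to-heart-rate dynamics are a two-phase
#' (second-order) plant whose gain and time constants are log-normally
#' perturbed around the nominal identified values (`k2 = 24.70` bpm/(m/s),
#' `tau21 = 18.60` s, `tau22 = 37.95` s) with coefficient of variation `cv`
#' and mean equal to the nominal value. Ages are uniform on 23-57 years and
#' resting heart rates uniform on 60-80 bpm. Deterministic in `seed`.
#'
#' @param n Number of participants; at least 1.
#' @param seed Integer seed.
#' @param cv Coefficient of variation of the plant parameters, in `[0, 1)`.
#' @param dist_sd,dist_cutoff_hz Heart-rate-variability disturbance standard
#'   deviation (bpm) and low-pass cutoff (Hz) assigned to every participant.
#' @param noise_sd Measurement noise standard deviation, bpm.
#' @return A tibble with one row per participant: `participant_id`, `k2`,
#'   `tau21`, `tau22`, `hr_rest`, `age`, `dist_sd`, `dist_cutoff_hz`,
#'   `noise_sd`, `seed` (per-participant stream seed).
#' @export
sample_cohort <- function(n, seed = 1, cv = 0.2, dist_sd = 2,
                          dist_cutoff_hz = 0.05, noise_sd = 1) {
  stopifnot(n >= 1, cv >= 0, cv < 1)
  old <- .Random.seed_safe(); on.exit(.restore_seed(old), add = TRUE)
  set.seed(seed)
  rl <- function(nominal) {
    if (cv == 0) return(rep(nominal, n))
    sdlog <- sqrt(log(1 + cv^2))
    nominal * exp(rnorm(n, mean = -sdlog^2 / 2, sd = sdlog))
  }
  k2 <- rl(24.70)
  tau21 <- rl(18.60)
  tau22 <- rl(37.95)
  swap <- tau21 > tau22
  tmp <- tau21[swap]; tau21[swap] <- tau22[swap]; tau22[swap] <- tmp
  tibble::tibble(
    participant_id = sprintf("P%02d", seq_len(n)),
    k2 = k2, tau21 = tau21, tau22 = tau22,
    hr_rest = runif(n, 60, 80),
    age = runif(n, 23, 57),
    dist_sd = dist_sd, dist_cutoff_hz = dist_cutoff_hz, noise_sd = noise_sd,
    seed = sample.int(.Machine$integer.max %/% 4L, n))
}

#' Run the paired two-controller experiment in silico
#'
#' For every participant, simulates one session with the first-order-model
#' compensator `C1` and one with the two-phase-model compensator `C2`. Both
#' controllers are designed from the fixed nominal plant models (one average
#' model serves all participants, as in the study), never from the
#' participant's true dynamics, and the two arms of each pair share identical
#' disturbance and noise realizations so the comparison is matched.
#'
#' @param cohort A tibble from [sample_cohort()].
#' @param proto A [protocol_spec()].
#' @param rise_time_s 10-90% rise time of the target tracking response, s.
#' @param u_min,u_max Treadmill speed limits, m/s.
#' @param keep_sessions Keep the full `hr_session` objects (list-column)?
#' @return A tibble with one row per (participant, controller): columns
#'   `participant_id`, `controller` (`"C1"`/`"C2"`), `rmse_bpm`,
#'   `p_grad_u_m2s2`, `n_samples`, and optionally `session`.
#' @export
run_paired_experiment <- function(cohort, proto = protocol_spec(),
                                  rise_time_s = 150,
                                  u_min = 0.5, u_max = 6.0,
                                  keep_sessions = FALSE) {
  stopifnot(nrow(cohort) >= 1)
  T_cl <- design_Tcl(rise_time_s)
  designs <- list(
    C1 = synthesize_constant_U(nominal_plant(1)),
    C2 = synthesize_constant_U(nominal_plant(2)))
  pfs <- lapply(designs, function(dn) design_prefilter(dn$T, T_cl))
  n_t <- as.integer(proto$measurement_s)
  rows <- purrr::map(seq_len(nrow(cohort)), function(i) {
    tr <- as.list(cohort[i, ])
    d <- gen_hrv_disturbance(n_t, fs = proto$hr_sample_hz, sd = tr$dist_sd,
                             cutoff_hz = tr$dist_cutoff_hz, seed = tr$seed)
    old <- .Random.seed_safe(); on.exit(.restore_seed(old), add = TRUE)
    set.seed(tr$seed + 1L)
    nn <- if (tr$noise_sd > 0) rnorm(n_t, sd = tr$noise_sd) else numeric(n_t)
    purrr::map(c("C1", "C2"), function(lab) {
      ses <- simulate_session(tr, designs[[lab]], pfs[[lab]], proto,
                              u_min = u_min, u_max = u_max, d = d, n = nn)
      out <- session_outcomes(ses)
      row <- tibble::tibble(participant_id = tr$participant_id,
                            controller = lab,
                            rmse_bpm = out$rmse_bpm,
                            p_grad_u_m2s2 = out$p_grad_u_m2s2,
                            n_samples = out$n_samples)
      if (keep_sessions) row$session <- list(ses)
      row
    })
  })
  dplyr::bind_rows(purrr::flatten(rows))
}
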