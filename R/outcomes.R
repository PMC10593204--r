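# Outcome measures over the evaluation window and the paired comparison.

#' Number of control-rate samples in the evaluation window
#'
#' The window `[eval_start_s, eval_end_s]` inclusive on the control-rate grid
#' holds `(eval_end - eval_start)/Ts + 1` samples: 361 for 295-2095 s and 301
#' for the truncated 295-1795 s variant at a 5 s control interval.
#'
#' @param proto A [protocol_spec()].
#' @return Integer sample count N.
#' @export
eval_window_samples <- function(proto) {
  Ts <- proto$control_Ts
  span <- proto$eval_end_s - proto$eval_start_s
  if (abs(span / Ts - round(span / Ts)) > 1e-9 ||
      abs(proto$eval_start_s / Ts - round(proto$eval_start_s / Ts)) > 1e-9) {
    stop("evaluation window is not aligned to the control-rate grid",
         call. = FALSE)
  }
  as.integer(round(span / Ts)) + 1L
}

#' Root-mean-square tracking error
#'
#' `RMSE = sqrt(mean((hr_sim - hr_meas)^2))` over exactly the evaluation
#' window samples of the aligned control-rate series.
#'
#' @param hr_meas Measured heart rate at the control rate, bpm.
#' @param hr_sim Nominal simulated heart-rate response at the control rate,
#'   bpm (a constant target during the evaluation window of a constant-target
#'   protocol, or the full tracking-response trajectory).
#' @param window Logical or integer index selecting the window samples;
#'   default uses all samples.
#' @return RMSE in bpm.
#' @export
compute_rmse <- function(hr_meas, hr_sim, window = NULL) {
  if (length(hr_sim) == 1) hr_sim <- rep(hr_sim, length(hr_meas))
  stopifnot(length(hr_meas) == length(hr_sim))
  if (!is.null(window)) {
    hr_meas <- hr_meas[window]; hr_sim <- hr_sim[window]
  }
  if (length(hr_meas) == 0) stop("empty evaluation window", call. = FALSE)
  sqrt(mean((hr_sim - hr_meas)^2))
}

#' Average power of changes in the control signal
#'
#' `P_grad_u = mean of squared successive differences` of the commanded speed
#' over the window, with divisor `N - 1` for the `N - 1` differences — the
#' measure of how dynamic a controller is.
#'
#' @param u Commanded speed at the control rate, m/s.
#' @param window Optional index selecting the window samples.
#' @return Power in m^2/s^2.
#' @export
compute_p_grad_u <- function(u, window = NULL) {
  if (!is.null(window)) u <- u[window]
  if (length(u) < 2) stop("need at least 2 samples", call. = FALSE)
  mean(diff(u)^2)
}

#' Evaluation-window outcomes of a simulated session
#'
#' Computes RMSE and the control-signal power of an [simulate_session()]
#' result over the protocol's evaluation window at the control rate. Because
#' the target is constant and the tracking-response transient has settled
#' before the window opens, the nominal simulated response is taken as the
#' constant target for the RMSE (the tracking trajectory is retained in the
#' series for transient analysis).
#'
#' @param session An `hr_session`.
#' @param hr_sim_mode `"target"` (constant target, the outcome convention) or
#'   `"trajectory"` (full tracking-response trajectory).
#' @return A one-row tibble: `rmse_bpm`, `p_grad_u_m2s2`, `n_samples`.
#' @export
session_outcomes <- function(session, hr_sim_mode = c("target", "trajectory")) {
  hr_sim_mode <- match.arg(hr_sim_mode)
  proto <- session$proto
  ctl <- session$control
  win <- ctl$t_s >= proto$eval_start_s & ctl$t_s <= proto$eval_end_s
  n_exp <- eval_window_samples(proto)
  if (sum(win) != n_exp) {
    stop(sprintf("evaluation window has %d samples, expected %d",
                 sum(win), n_exp), call. = FALSE)
  }
  ref <- if (hr_sim_mode == "target") session$target_hr_bpm else ctl$hr_sim_bpm
  tibble::tibble(
    rmse_bpm = compute_rmse(ctl$hr_meas_avg_bpm, ref, win),
    p_grad_u_m2s2 = compute_p_grad_u(ctl$speed_cmd_mps, win),
    n_samples = n_exp)
}

#' Lilliefors-corrected Kolmogorov-Smirnov normality test
#'
#' KS statistic of the sample against a normal distribution with mean and
#' standard deviation estimated from the same sample; the p-value comes from a
#' seeded Monte-Carlo null (normal samples of the same size, subjected to the
#' same estimation), which is exact up to Monte-Carlo error at any sample
#' size.
#'
#' @param x Numeric sample, length >= 4, non-degenerate.
#' @param n_mc Number of Monte-Carlo null replicates.
#' @param seed Integer seed for the null simulation.
#' @return p-value in `[0, 1]`.
#' @export
lilliefors_normality <- function(x, n_mc = 10000, seed = 1) {
  if (length(x) < 4) stop("need at least 4 observations", call. = FALSE)
  if (sd(x) == 0) stop("degenerate sample (zero variance)", call. = FALSE)
  n <- length(x)
  stat <- lilliefors_stat(x)
  old <- .Random.seed_safe(); on.exit(.restore_seed(old), add = TRUE)
  set.seed(seed)
  null_mat <- matrix(rnorm(n * n_mc), nrow = n)
  null_stats <- apply(null_mat, 2, lilliefors_stat)
  (1 + sum(null_stats >= stat)) / (n_mc + 1)
}

lilliefors_stat <- function(x) {
  n <- length(x)
  xs <- sort(x)
  f <- pnorm(xs, mean = mean(x), sd = sd(x))
  max(max(seq_len(n) / n - f), max(f - (seq_len(n) - 1) / n))
}

#' One-sided paired t-test comparison of the two controllers
#'
#' Tests the mean of the paired differences `C2 - C1` against zero in the
#' prespecified direction (`"less"` for RMSE, `"greater"` for control-signal
#' power), at significance level 0.05. Reports per-arm descriptives, the mean
#' difference, the one-sided 95% confidence half-line, and the p-value,
#' mirroring the structure of a paired-outcome summary table.
#'
#' @param x_c1,x_c2 Paired outcome vectors (same participants, same order).
#' @param direction Alternative for `mean(C2 - C1)`: `"less"` or `"greater"`.
#' @param outcome Optional label carried into the result.
#' @param normality_p Optional pre-computed normality p-value of the
#'   differences (e.g. from [lilliefors_normality()]).
#' @return A one-row tibble of class `hr_comparison`: `outcome`, `n_pairs`,
#'   `mean_c1`, `sd_c1`, `mean_c2`, `sd_c2`, `mean_diff`, `ci_lower`,
#'   `ci_upper`, `p_value`, `normality_p`.
#' @export
paired_one_sided_t <- function(x_c1, x_c2, direction = c("less", "greater"),
                               outcome = NA_character_,
                               normality_p = NA_real_) {
  direction <- match.arg(direction)
  if (length(x_c1) != length(x_c2)) stop("length mismatch", call. = FALSE)
  if (length(x_c1) < 2) stop("need at least 2 pairs", call. = FALSE)
  diffs <- x_c2 - x_c1
  if (sd(diffs) == 0) stop("zero-variance differences", call. = FALSE)
  tt <- t.test(x_c2, x_c1, paired = TRUE, alternative = direction,
               conf.level = 0.95)
  res <- tibble::tibble(
    outcome = outcome, n_pairs = length(diffs),
    mean_c1 = mean(x_c1), sd_c1 = sd(x_c1),
    mean_c2 = mean(x_c2), sd_c2 = sd(x_c2),
    mean_diff = mean(diffs),
    ci_lower = tt$conf.int[1], ci_upper = tt$conf.int[2],
    p_value = unname(tt$p.value), normality_p = normality_p)
  class(res) <- c("hr_comparison", class(res))
  res
}

#' Compare both outcomes between the two controller arms
#'
#' Takes the tidy outcome table of [run_paired_experiment()] and produces the
#' paired statistical summary: Lilliefors normality screening of the paired
#' differences followed by one-sided paired t-tests — RMSE tested for C2
#' being lower, control-signal power for C2 being higher.
#'
#' @param outcomes Tibble with columns `participant_id`, `controller`,
#'   `rmse_bpm`, `p_grad_u_m2s2`.
#' @param n_mc,seed Monte-Carlo settings for [lilliefors_normality()].
#' @return A two-row `hr_comparison` tibble (one row per outcome).
#' @export
compare_controllers <- function(outcomes, n_mc = 10000, seed = 1) {
  wide <- outcomes |>
    dplyr::select("participant_id", "controller", "rmse_bpm", "p_grad_u_m2s2") |>
    tidyr::pivot_wider(names_from = "controller",
                       values_from = c("rmse_bpm", "p_grad_u_m2s2"))
  one <- function(col, direction, label, sub_seed) {
    c1 <- wide[[paste0(col, "_C1")]]
    c2 <- wide[[paste0(col, "_C2")]]
    np <- if (length(c1) >= 4) {
      lilliefors_normality(c2 - c1, n_mc = n_mc, seed = sub_seed)
    } else NA_real_
    paired_one_sided_t(c1, c2, direction, outcome = label, normality_p = np)
  }
  res <- dplyr::bind_rows(
    one("rmse_bpm", "less", "rmse_bpm", seed),
    one("p_grad_u_m2s2", "greater", "p_grad_u_m2s2", seed + 1L))
  class(res) <- c("hr_comparison", class(res))
  res
}
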