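# Readers and writers: design reports (JSON), scenarios (YAML), time series
# and outcome tables (CSV). All artifacts are diff-able plain text.

#' Write and read a design report as JSON
#'
#' The report stores the plant, `g0'`, compensator, sensitivity functions,
#' prefilter and target response, with coefficient vectors in descending
#' powers of s at full precision and SI units (s, m/s, bpm).
#'
#' @param design A `compensator_design`.
#' @param pf Optional `prefilter_design`.
#' @param path Output file path.
#' @return `write_design_json()` returns `path` invisibly; `read_design_json()`
#'   returns a list `(design, pf)`.
#' @export
write_design_json <- function(design, path, pf = NULL) {
  tf_list <- function(x) list(num = x$num, den = x$den)
  pl <- attr(design$plant, "params")
  obj <- list(
    plant = c(list(order = attr(design$plant, "order")), pl,
              tf_list(design$plant)),
    g0_prime = design$g0_prime,
    H_prime = design$H_prime,
    C = tf_list(design$C),
    S = tf_list(design$S),
    T = tf_list(design$T),
    U_const = design$U_const)
  if (!is.null(pf)) {
    obj$C_pf <- tf_list(pf$C_pf)
    obj$T_cl <- tf_list(pf$T_cl)
    obj$rise_time_target_s <- pf$rise_time_target
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_design_json
#' @export
read_design_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_tf_l <- function(l) tf(l$num, l$den)
  plant <- as_tf_l(obj$plant)
  attr(plant, "order") <- obj$plant$order
  design <- new_compensator_design(
    plant, obj$g0_prime, obj$H_prime,
    as_tf_l(obj$C), as_tf_l(obj$S), as_tf_l(obj$T))
  pf <- NULL
  if (!is.null(obj$C_pf)) {
    pf <- new_prefilter_design(as_tf_l(obj$T_cl), as_tf_l(obj$C_pf),
                               obj$rise_time_target_s %||% NA_real_)
  }
  list(design = design, pf = pf)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a simulation scenario from YAML
#'
#' Scenario files describe an in-silico experiment: nominal plant parameters,
#' cohort size/seed/variability, disturbance and noise levels, protocol
#' overrides and treadmill speed limits. Missing fields take the package
#' defaults.
#'
#' @param path Path to a YAML file.
#' @return A list with elements `cohort`, `disturbance`, `noise_sd_bpm`,
#'   `protocol` (a [protocol_spec()]), `saturation`, `rise_time_s`.
#' @export
read_scenario <- function(path) {
  # keep YAML 1.1 boolean-like scalars (notably the cohort key "n") literal
  raw <- yaml::read_yaml(path, handlers = list(
    "bool#yes" = function(x) x, "bool#no" = function(x) x))
  defaults <- list(
    cohort = list(n = 20, seed = 1, cv = 0.2),
    disturbance = list(sd_bpm = 2, cutoff_hz = 0.05),
    noise_sd_bpm = 1,
    protocol = list(),
    saturation = list(u_min = 0.5, u_max = 6.0),
    rise_time_s = 150)
  sc <- modifyList(defaults, raw %||% list())
  known <- names(defaults)
  unknown <- setdiff(names(sc), known)
  if (length(unknown) > 0) {
    stop("unknown scenario fields: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  sc$protocol <- do.call(protocol_spec, sc$protocol)
  sc
}

#' Run a full scenario: cohort, paired sessions, outcomes and comparison
#'
#' The end-to-end pipeline behind the `experiment` command: samples the
#' cohort, runs the matched paired experiment, and computes the outcome table
#' and the paired statistical comparison.
#'
#' @param scenario A list from [read_scenario()] (or of the same shape).
#' @param seed Optional global seed overriding the scenario's cohort seed.
#' @return A list: `cohort`, `outcomes` (tibble), `comparison`
#'   (`hr_comparison` tibble).
#' @export
run_scenario <- function(scenario, seed = NULL) {
  co <- scenario$cohort
  if (!is.null(seed)) co$seed <- seed
  cohort <- sample_cohort(co$n, seed = co$seed, cv = co$cv,
                          dist_sd = scenario$disturbance$sd_bpm,
                          dist_cutoff_hz = scenario$disturbance$cutoff_hz,
                          noise_sd = scenario$noise_sd_bpm)
  outcomes <- run_paired_experiment(cohort, scenario$protocol,
                                    rise_time_s = scenario$rise_time_s,
                                    u_min = scenario$saturation$u_min,
                                    u_max = scenario$saturation$u_max)
  comparison <- compare_controllers(outcomes, seed = co$seed)
  list(cohort = cohort, outcomes = outcomes, comparison = comparison)
}

session_csv_columns <- c("t_s", "hr_ref_bpm", "hr_ref_filt_bpm", "hr_true_bpm",
                         "hr_meas_bpm", "hr_sim_bpm", "speed_cmd_mps",
                         "disturbance_bpm", "noise_bpm")

#' Write and read session time series as CSV
#'
#' The CSV schema is `t_s, hr_ref_bpm, hr_ref_filt_bpm, hr_true_bpm,
#' hr_meas_bpm, hr_sim_bpm, speed_cmd_mps, disturbance_bpm, noise_bpm` at the
#' 1 Hz heart-rate sampling grid. Readers reject files whose columns deviate
#' from the schema.
#'
#' @param session An `hr_session` (or its `series` tibble).
#' @param path File path.
#' @return `write_session_csv()` returns `path` invisibly;
#'   `read_session_csv()` returns the series tibble.
#' @export
write_session_csv <- function(session, path) {
  series <- if (inherits(session, "hr_session")) session$series else session
  stopifnot(all(session_csv_columns %in% names(series)))
  write.csv(series[session_csv_columns], path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}

#' @rdname write_session_csv
#' @export
read_session_csv <- function(path) {
  df <- read.csv(path, check.names = TRUE)
  if (!identical(names(df), session_csv_columns)) {
    stop("time-series CSV columns do not match the expected schema: ",
         paste(session_csv_columns, collapse = ", "), call. = FALSE)
  }
  tibble::as_tibble(df)
}

#' Re-evaluate outcomes from a stored time-series CSV
#'
#' Reconstructs the control-rate series from the 1 Hz file (5-consecutive-
#' sample averaging of the measured heart rate; speed command read at the
#' control instants) and computes RMSE against the stored nominal simulated
#' response plus the control-signal power over the evaluation window.
#'
#' @param path Path to a CSV in the [write_session_csv()] schema.
#' @param proto A [protocol_spec()] fixing the evaluation window and rates.
#' @return A one-row tibble: `rmse_bpm`, `p_grad_u_m2s2`, `n_samples`.
#' @export
evaluate_timeseries <- function(path, proto = protocol_spec()) {
  series <- read_session_csv(path)
  Ts <- proto$control_Ts
  if (max(series$t_s) < proto$eval_end_s) {
    stop("file ends before the evaluation window", call. = FALSE)
  }
  is_ctl <- series$t_s %% Ts == 0
  ctl_t <- series$t_s[is_ctl]
  k_idx <- match(ctl_t, series$t_s)
  zbar <- vapply(k_idx, function(k)
    mean(series$hr_meas_bpm[max(1, k - Ts + 1):k]), numeric(1))
  u <- series$speed_cmd_mps[k_idx]
  hr_sim <- series$hr_sim_bpm[k_idx]
  win <- ctl_t >= proto$eval_start_s & ctl_t <= proto$eval_end_s
  n_exp <- eval_window_samples(proto)
  if (sum(win) != n_exp) {
    stop(sprintf("evaluation window has %d samples, expected %d",
                 sum(win), n_exp), call. = FALSE)
  }
  tibble::tibble(
    rmse_bpm = compute_rmse(zbar, hr_sim, win),
    p_grad_u_m2s2 = compute_p_grad_u(u, win),
    n_samples = n_exp)
}

#' Write outcome and comparison tables
#'
#' @param outcomes Outcome tibble from [run_paired_experiment()].
#' @param comparison `hr_comparison` tibble from [compare_controllers()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_outcomes_csv <- function(outcomes, path) {
  write.csv(outcomes[c("participant_id", "controller", "rmse_bpm",
                       "p_grad_u_m2s2")], path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}

#' @rdname write_outcomes_csv
#' @export
write_comparison_json <- function(comparison, path) {
  jsonlite::write_json(as.data.frame(comparison), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
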