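# broom-style tidiers for the package's result objects.

#' Tidy a compensator design into a coefficient table
#'
#' @param x A `compensator_design`.
#' @param ... Unused.
#' @return A tibble with one row per coefficient: `component` (C/S/T/plant),
#'   `part` (num/den), `power` (power of s), `value`.
#' @export
tidy.compensator_design <- function(x, ...) {
  one <- function(tf_obj, comp) {
    dplyr::bind_rows(
      tibble::tibble(component = comp, part = "num",
                     power = rev(seq_along(tf_obj$num)) - 1L,
                     value = tf_obj$num),
      tibble::tibble(component = comp, part = "den",
                     power = rev(seq_along(tf_obj$den)) - 1L,
                     value = tf_obj$den))
  }
  dplyr::bind_rows(one(x$plant, "plant"), one(x$C, "C"),
                   one(x$S, "S"), one(x$T, "T"))
}

#' @rdname tidy.compensator_design
#' @export
glance.compensator_design <- function(x, ...) {
  tibble::tibble(
    plant_order = poly_deg(x$plant$den),
    g0_prime = x$g0_prime,
    U_const = x$U_const,
    U_const_db = 20 * log10(abs(x$U_const)),
    C_num_degree = poly_deg(x$C$num),
    C_den_degree = poly_deg(x$C$den),
    integral_action = any(abs(poly_roots(x$C$den)) < 1e-9))
}

#' Tidy a simulated session
#'
#' @param x An `hr_session`.
#' @param rate `"hr"` for the 1 Hz series, `"control"` for the 0.2 Hz series.
#' @param ... Unused.
#' @return The corresponding tibble.
#' @export
tidy.hr_session <- function(x, rate = c("hr", "control"), ...) {
  rate <- match.arg(rate)
  if (rate == "hr") x$series else x$control
}

#' @rdname tidy.hr_session
#' @export
glance.hr_session <- function(x, ...) {
  o <- session_outcomes(x)
  tibble::tibble(
    target_hr_bpm = x$target_hr_bpm, hr_rest_bpm = x$hr_rest_bpm,
    duration_s = nrow(x$series),
    rmse_bpm = o$rmse_bpm, p_grad_u_m2s2 = o$p_grad_u_m2s2,
    n_eval_samples = o$n_samples,
    saturated_frac = mean(x$control$speed_cmd_mps <= x$u_min |
                            x$control$speed_cmd_mps >= x$u_max))
}
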