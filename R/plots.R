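# ggplot2 graphics for designs, sessions and comparisons.

#' Sensitivity-magnitude (Bode) plot of one or more designs
#'
#' Magnitudes in dB of the input sensitivity U, sensitivity S and
#' complementary sensitivity T over 1e-4 to 1 Hz, with the four HRV analysis
#' band edges (1/300, 0.04, 0.15, 0.4 Hz) marked.
#'
#' @param ... Named `compensator_design` objects (names become labels).
#' @param n Frequency grid size.
#' @return A ggplot object.
#' @export
plot_sensitivities <- function(..., n = 300) {
  designs <- list(...)
  if (is.null(names(designs)) || any(names(designs) == "")) {
    names(designs) <- paste0("design", seq_along(designs))
  }
  df <- purrr::imap(designs, function(d, nm) {
    dplyr::mutate(bode_table(d, n = n), design = nm)
  }) |> dplyr::bind_rows() |>
    tidyr::pivot_longer(c("U_db", "S_db", "T_db"),
                        names_to = "fn", values_to = "mag_db") |>
    dplyr::mutate(fn = factor(.data$fn, levels = c("U_db", "S_db", "T_db"),
                              labels = c("U", "S", "T")))
  ggplot2::ggplot(df, ggplot2::aes(.data$freq_hz, .data$mag_db,
                                   colour = .data$design)) +
    ggplot2::geom_vline(xintercept = unname(hrv_band_edges()),
                        linetype = "dashed", colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~fn, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "frequency (Hz)", y = "magnitude (dB)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a simulated closed-loop session
#'
#' Two panels: heart rate (target, filtered reference, measured, nominal
#' simulated response) and the commanded treadmill speed, with the evaluation
#' window shaded.
#'
#' @param object An `hr_session`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hr_session <- function(object, ...) {
  s <- object$series
  proto <- object$proto
  hr <- tidyr::pivot_longer(
    s[c("t_s", "hr_ref_bpm", "hr_meas_bpm", "hr_sim_bpm")],
    -"t_s", names_to = "signal", values_to = "bpm")
  df <- dplyr::bind_rows(
    dplyr::mutate(hr, panel = "heart rate (bpm)",
                  value = .data$bpm),
    tibble::tibble(t_s = s$t_s, signal = "speed_cmd_mps",
                   panel = "speed command (m/s)", value = s$speed_cmd_mps))
  ggplot2::ggplot(df, ggplot2::aes(.data$t_s, .data$value,
                                   colour = .data$signal)) +
    ggplot2::annotate("rect", xmin = proto$eval_start_s,
                      xmax = proto$eval_end_s, ymin = -Inf, ymax = Inf,
                      alpha = 0.08) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot paired outcomes of the two controllers
#'
#' Dot plot of the per-participant outcomes with lines connecting the paired
#' samples, one facet per outcome measure.
#'
#' @param outcomes Tibble from [run_paired_experiment()].
#' @return A ggplot object.
#' @export
plot_outcomes <- function(outcomes) {
  df <- tidyr::pivot_longer(
    outcomes[c("participant_id", "controller", "rmse_bpm", "p_grad_u_m2s2")],
    c("rmse_bpm", "p_grad_u_m2s2"),
    names_to = "outcome", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$controller, .data$value)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$participant_id),
                       colour = "grey70") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$controller)) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.3,
                          colour = "red") +
    ggplot2::facet_wrap(~outcome, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::guides(colour = "none") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
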