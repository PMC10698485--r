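#' Plot a posture solution
#'
#' Roll-angle time series with both branches in the background, the chosen
#' branch emphasized, and interpolated stretches (headings at magnetic
#' north/south, or out-of-range samples) highlighted.
#'
#' @param object A `posture_solution` from [solve_posture()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.posture_solution <- function(object, ...) {
  branches <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("t", "roll_plus", "roll_minus")],
    -"t", names_to = "solution", names_prefix = "roll_",
    values_to = "roll_branch")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$t)) +
    ggplot2::geom_line(
      data = branches,
      ggplot2::aes(y = .data$roll_branch, colour = .data$solution),
      alpha = 0.35, na.rm = TRUE) +
    ggplot2::geom_line(ggplot2::aes(y = .data$roll), na.rm = TRUE) +
    ggplot2::geom_point(
      data = function(d) d[d$interpolated, ],
      ggplot2::aes(y = .data$roll), colour = "red", size = 0.4,
      na.rm = TRUE) +
    ggplot2::labs(x = "time (s)", y = "roll (deg)",
                  colour = "yaw branch") +
    ggplot2::theme_minimal()
}

#' Plot a pitch-sensitivity error grid
#'
#' Roll-error surface over magnetic heading and roll, faceted by true pitch;
#' invalid cells (no yaw solution, |h_x| > 1) are left blank.
#'
#' @param object A `pitch_error_grid` from [pitch_error_grid()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pitch_error_grid <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$heading_mag, y = .data$roll,
                               fill = .data$error)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(ggplot2::vars(.data$pitch),
                        labeller = ggplot2::label_both) +
    ggplot2::scale_fill_viridis_c(na.value = "grey85") +
    ggplot2::labs(x = "magnetic heading (deg)", y = "true roll (deg)",
                  fill = "|roll error| (deg)") +
    ggplot2::theme_minimal()
}

#' Overlay an estimated roll series on a reference series
#'
#' @param estimate,reference Data frames with columns `t`, `roll`.
#' @return A ggplot.
#' @export
plot_roll_comparison <- function(estimate, reference) {
  both <- dplyr::bind_rows(
    dplyr::mutate(estimate[, c("t", "roll")], series = "estimate"),
    dplyr::mutate(reference[, c("t", "roll")], series = "reference")
  )
  ggplot2::ggplot(both, ggplot2::aes(x = .data$t, y = .data$roll,
                                     colour = .data$series)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::labs(x = "time (s)", y = "roll (deg)", colour = NULL) +
    ggplot2::theme_minimal()
}
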