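# ggplot2 graphics for traces, fits and study tables.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a loading history
#' @param object A [loading_history()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.vf_loading <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s, y = .data$strain)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "engineering shear strain") +
    ggplot2::theme_minimal()
}

#' Plot a stress or force trace
#' @param object A stress (`time_s`, `stress_pa`) or force (`time_s`,
#'   `force_n`) trace.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.vf_stress_trace <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s, y = .data$stress_pa)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "shear stress (Pa)") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.vf_stress_trace
#' @export
autoplot.vf_force_trace <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s, y = .data$force_n)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "shear force (N)") +
    ggplot2::theme_minimal()
}

#' Plot an FE solution's reaction-force trace
#' @param object A [solve_shear()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fe_solution <- function(object, ...) {
  autoplot.vf_force_trace(object$force_trace) +
    ggplot2::labs(title = sprintf("%d-element %s specimen",
                                  object$mesh$n_elements,
                                  object$mesh$geometry$shape))
}

#' Plot the fitted relaxation modulus of a fit result
#' @param object A `fit_result`.
#' @param times Evaluation times (s).
#' @param ... Unused.
#' @return A ggplot of G(t) on log time.
#' @export
autoplot.fit_result <- function(object,
                                times = exp(seq(log(1e-3), log(4),
                                                length.out = 200)),
                                ...) {
  df <- tibble::tibble(time_s = times,
                       g_pa = relaxation_modulus(object$material, times))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$g_pa)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "time (s)", y = "G(t) (Pa)", title = object$mode) +
    ggplot2::theme_minimal()
}

#' Bar chart of average moduli by fit mode
#' @param moduli_summary Tibble from [run_mode_comparison()].
#' @return A ggplot.
#' @export
plot_moduli <- function(moduli_summary) {
  df <- tidyr::pivot_longer(moduli_summary,
                            cols = c("mean_g_inf", "mean_g0"),
                            names_to = "modulus", values_to = "pa")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mode, y = .data$pa,
                                   fill = .data$modulus)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "average modulus (Pa)") +
    ggplot2::theme_minimal()
}

#' Average reduced relaxation curves by fit mode
#' @param curves Tibble from [relaxation_curves()].
#' @return A ggplot on log time.
#' @export
plot_relaxation <- function(curves) {
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$time_s, y = .data$g_reduced,
                                       colour = .data$mode)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "time (s)", y = "G(t) / G_inf") +
    ggplot2::theme_minimal()
}

#' Histogram of the element shear-strain census
#' @param census Tibble from [strain_census()].
#' @return A ggplot.
#' @export
plot_census <- function(census) {
  ggplot2::ggplot(census, ggplot2::aes(x = .data$bin, y = .data$fraction)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "element shear strain at peak", y = "fraction of elements") +
    ggplot2::theme_minimal()
}
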