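#' Stress response to a perfect strain step
#'
#' For an idealised step to strain `eps0` at t = 0 the linear-viscoelastic
#' shear stress is \eqn{\sigma(t) = \varepsilon_0 G(t)}: the relaxation
#' modulus scaled by the held strain. This is the model used by the
#' "without ramp" identification mode, which treats the finite-time ramp of a
#' real test as instantaneous.
#'
#' @param material A [prony_material()].
#' @param eps0 Held engineering shear strain, in (0, 1] (0 allowed and gives
#'   an identically zero trace).
#' @param times Sample times (s), non-negative.
#' @return A stress trace tibble (`time_s`, `stress_pa`).
#' @export
step_response <- function(material, eps0, times) {
  stopifnot(inherits(material, "prony_material"))
  if (eps0 < 0 || eps0 > 1) stop("`eps0` must lie in [0, 1].")
  if (any(times < 0)) stop("`times` must be non-negative.")
  new_stress_trace(times, eps0 * relaxation_modulus(material, times))
}

#' Recursive hereditary-integral stress update
#'
#' Computes the shear stress response to an arbitrary sampled strain history
#' by the standard recursive update of the Boltzmann convolution
#' \eqn{\sigma(t) = \int_0^t G(t-\tau)\,\dot\varepsilon(\tau)\,d\tau}.
#' Strain is taken piecewise linear between samples (constant rate per step),
#' for which the within-step integral of each exponential term has the closed
#' form used here:
#' \deqn{h_i(t+\Delta t) = e^{-\beta_i \Delta t} h_i(t) +
#'   \frac{\Delta\varepsilon}{\Delta t}\,
#'   \bigl(1 - e^{-\beta_i \Delta t}\bigr)\,\frac{G_i}{\beta_i},}
#' \deqn{\sigma(t+\Delta t) = G_\infty\,\varepsilon(t+\Delta t) +
#'   \sum_i h_i(t+\Delta t),}
#' with \eqn{h_i(0) = 0}. Non-uniform time steps are supported, so the hold
#' phase may be sampled on a logarithmic grid.
#'
#' @param material A [prony_material()].
#' @param loading A [loading_history()] (or any tibble with `time_s` and
#'   `strain` columns, strictly increasing time).
#' @return A stress trace tibble (`time_s`, `stress_pa`), same length as
#'   `loading`.
#' @export
stress_recursive <- function(material, loading) {
  stopifnot(inherits(material, "prony_material"))
  time <- loading$time_s
  strain <- loading$strain
  n <- length(time)
  stopifnot(n >= 1L, length(strain) == n)
  dt <- diff(time)
  if (any(dt <= 0)) stop("Time steps must be strictly positive.")
  nb <- length(material$beta)
  h <- numeric(nb)
  sigma <- numeric(n)
  sigma[1] <- material$g_inf * strain[1]  # h_i(0) = 0
  for (k in seq_len(n - 1L)) {
    d <- dt[k]
    rate <- (strain[k + 1L] - strain[k]) / d
    decay <- exp(-material$beta * d)
    h <- decay * h + rate * (1 - decay) * material$g_terms / material$beta
    sigma[k + 1L] <- material$g_inf * strain[k + 1L] + sum(h)
  }
  new_stress_trace(time, sigma)
}

#' Brute-force convolution stress (trapezoidal quadrature reference)
#'
#' Direct trapezoidal quadrature of the hereditary integral
#' \eqn{\sigma(t) = \int_0^t G(t-\tau)\dot\varepsilon(\tau) d\tau} on the
#' loading's own grid: on each sampling interval the strain rate is the
#' piecewise slope and the kernel \eqn{G(t-\tau)} is integrated by the
#' trapezoid rule. Quadratic cost in the number of samples; used as an
#' independent reference for the O(n) recursive update, not for production.
#'
#' @inheritParams stress_recursive
#' @param at Optional indices into the loading grid at which to evaluate the
#'   stress (default: all samples). The integral still runs over the full
#'   grid up to each requested time; requesting a few times keeps the cost
#'   linear even on very fine grids.
#' @return A stress trace tibble (restricted to `at` when given).
#' @keywords internal
#' @export
stress_quadrature <- function(material, loading, at = NULL) {
  stopifnot(inherits(material, "prony_material"))
  time <- loading$time_s
  strain <- loading$strain
  n <- length(time)
  dt <- diff(time)
  if (any(dt <= 0)) stop("Time steps must be strictly positive.")
  rate <- diff(strain) / dt
  idx <- if (is.null(at)) seq_len(n) else sort(unique(as.integer(at)))
  sigma <- numeric(length(idx))
  for (m in seq_along(idx)) {
    k <- idx[m]
    if (k == 1L) {
      sigma[m] <- material$g_inf * strain[1]
      next
    }
    j <- seq_len(k - 1L)
    g_lo <- relaxation_modulus(material, time[k] - time[j])
    g_hi <- relaxation_modulus(material, time[k] - time[j + 1L])
    sigma[m] <- sum(dt[j] / 2 * (g_lo + g_hi) * rate[j])
  }
  new_stress_trace(time[idx], sigma)
}
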