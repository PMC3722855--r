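#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fit result
#'
#' One row per identified shear coefficient, with its fixed decay rate where
#' applicable.
#'
#' @param x A `fit_result` from [fit_analytical()] or [fit_fe_srsm()].
#' @param ... Unused.
#' @return Tibble with `term`, `estimate` (Pa), `beta` (1/s, `NA` for
#'   `g_inf`).
#' @export
tidy.fit_result <- function(x, ...) {
  tibble::tibble(
    term = c("g_inf", paste0("g", seq_along(x$material$g_terms))),
    estimate = c(x$material$g_inf, x$material$g_terms),
    beta = c(NA_real_, x$material$beta)
  )
}

#' Glance at a fit result
#'
#' @inheritParams tidy.fit_result
#' @return One-row tibble: `mode`, `sse`, `g_inf`, `g0`, `n_eval`,
#'   `converged`.
#' @export
glance.fit_result <- function(x, ...) {
  tibble::tibble(
    mode = x$mode, sse = x$sse, g_inf = x$material$g_inf,
    g0 = x$material$g0, n_eval = x$n_eval, converged = x$converged
  )
}
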