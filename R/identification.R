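# Inverse identification of Prony shear moduli from ramp-and-hold traces:
# two analytical (uniform-strain, 1-D) modes and the FE-based mode in srsm.R.

#' Convert between force/displacement traces and stress/strain
#'
#' The analytical identification works in stress-strain space under the
#' uniform-strain assumption: shear stress = force / cross-sectional area,
#' engineering shear strain = lateral displacement / specimen height.
#'
#' @param trace A force trace tibble (`time_s`, `force_n`).
#' @param geometry A [specimen_geometry()].
#' @return `force_to_stress()`: a stress trace; `displacement_to_strain()`:
#'   a [loading_history()].
#' @export
force_to_stress <- function(trace, geometry) {
  stopifnot(inherits(geometry, "specimen_geometry"))
  if (geometry$area <= 0) stop("Geometry has zero cross-sectional area.")
  new_stress_trace(trace$time_s, trace$force_n / geometry$area)
}

#' @rdname force_to_stress
#' @param displacement Tibble with `time_s` and `displacement_m` columns.
#' @param ramp_time Ramp duration (s); defaults to the time of first reaching
#'   the maximum displacement.
#' @export
displacement_to_strain <- function(displacement, geometry, ramp_time = NULL) {
  stopifnot(inherits(geometry, "specimen_geometry"))
  if (geometry$height <= 0) stop("Geometry has zero height.")
  strain <- displacement$displacement_m / geometry$height
  if (is.null(ramp_time)) {
    ramp_time <- displacement$time_s[which.max(strain)][1]
  }
  loading_history(displacement$time_s, strain, ramp_time = ramp_time,
                  hold_strain = max(strain))
}

#' Objective specification: the log-time comparison grid
#'
#' The fitting objective is the sum of squared errors between model and data
#' evaluated at `n_points` equidistant points on the logarithmic time scale
#' between `t_min` and the end of the data.
#'
#' @param n_points Number of comparison points (default 200).
#' @param t_min First positive comparison time (s, default 1e-3; a log grid
#'   cannot include t = 0).
#' @return A list of class `objective_spec`.
#' @export
objective_spec <- function(n_points = 200L, t_min = 1e-3) {
  if (n_points < 10L) stop("`n_points` must be at least 10.")
  if (t_min <= 0) stop("`t_min` must be positive.")
  structure(list(n_points = as.integer(n_points), t_min = t_min),
            class = "objective_spec")
}

objective_grid <- function(spec, t_end) {
  if (t_end <= spec$t_min) stop("Trace does not extend past `t_min`.")
  exp(seq(log(spec$t_min), log(t_end), length.out = spec$n_points))
}

#' Sum-of-squared-errors objective on the log-time grid
#'
#' Interpolates both traces linearly onto the log-spaced comparison grid and
#' returns \eqn{\sum_k (model_k - data_k)^2}. Units are Pa^2 when stress
#' traces are compared and N^2 for force traces; both traces must be of the
#' same kind.
#'
#' @param model_trace,data_trace Trace tibbles (`time_s` plus one value
#'   column, both of the same kind).
#' @param spec An [objective_spec()].
#' @return Non-negative scalar.
#' @export
sse_objective <- function(model_trace, data_trace, spec = objective_spec()) {
  t_end <- min(max(model_trace$time_s), max(data_trace$time_s))
  if (max(model_trace$time_s) < spec$t_min || max(data_trace$time_s) < spec$t_min) {
    stop("Traces do not overlap the comparison grid.")
  }
  grid <- objective_grid(spec, t_end)
  mcol <- trace_value_col(model_trace)
  dcol <- trace_value_col(data_trace)
  if (mcol != dcol) stop("Model and data traces must be of the same kind.")
  m <- stats::approx(model_trace$time_s, model_trace[[mcol]], xout = grid,
                     rule = 2)$y
  d <- stats::approx(data_trace$time_s, data_trace[[dcol]], xout = grid,
                     rule = 2)$y
  sum((m - d)^2)
}

#' Analytical (uniform-strain) identification of Prony shear moduli
#'
#' Fits the four shear coefficients (G_inf, G_1, G_2, G_3; decay rates fixed
#' at 1, 10, 100 per second) of the linear-viscoelastic model to a measured
#' shear-stress trace by minimising the log-time SSE with a bounded
#' quasi-Newton method (L-BFGS-B), with seeded multi-start to guard against
#' local minima.
#'
#' Two modes mirror the two conventions in the step-and-hold literature:
#' * `"with_ramp"` — the model stress is the recursive hereditary-integral
#'   response to the full sampled loading (ramp included), fitted to the
#'   whole trace;
#' * `"no_ramp"` — the ramp is idealised as a perfect step: time is re-zeroed
#'   at the end of the ramp and the model \eqn{\sigma(t') = \varepsilon_0
#'   G(t')} is fitted to the post-ramp (relaxation) data only.
#'
#' @param data A stress trace tibble (`time_s`, `stress_pa`).
#' @param loading The [loading_history()] applied during the test.
#' @param mode `"with_ramp"` or `"no_ramp"`.
#' @param spec An [objective_spec()].
#' @param beta Fixed decay rates (1/s).
#' @param bulk_modulus Bulk modulus carried into the fitted material (Pa).
#' @param start Optional numeric length-4 starting vector
#'   `(G_inf, G_1, G_2, G_3)`; default starts are spread over the modulus
#'   range.
#' @param n_starts Number of multi-start runs (default 5).
#' @param upper Upper bound on each modulus (Pa, default 1e5).
#' @param seed Integer seed for the multi-start draw.
#' @return A `fit_result` object; see [tidy.fit_result()] / `glance()`.
#' @export
fit_analytical <- function(data, loading,
                           mode = c("with_ramp", "no_ramp"),
                           spec = objective_spec(),
                           beta = c(1, 10, 100),
                           bulk_modulus = 2.1e9,
                           start = NULL, n_starts = 5L, upper = 1e5,
                           seed = 1L) {
  mode <- match.arg(mode)
  ramp_time <- attr(loading, "ramp_time")
  hold_strain <- attr(loading, "hold_strain")

  if (mode == "no_ramp") {
    post <- data$time_s >= ramp_time - 1e-12
    data_fit <- new_stress_trace(pmax(data$time_s[post] - ramp_time, 0),
                                 data$stress_pa[post])
    model_fun <- function(g) {
      step_response(material_from_g(g, beta, bulk_modulus), hold_strain,
                    data_fit$time_s)
    }
  } else {
    data_fit <- data
    # evaluate the recursive model on a compact grid: the ramp knots plus the
    # log-time comparison points. The recursion is exact for piecewise-linear
    # strain, so this loses nothing relative to the full sampling grid while
    # keeping each objective evaluation cheap.
    t_end <- min(max(data$time_s), max(loading$time_s))
    model_times <- sort(unique(c(
      seq(0, ramp_time, length.out = 101L),
      objective_grid(spec, t_end), t_end
    )))
    model_strain <- stats::approx(loading$time_s, loading$strain,
                                  xout = model_times, rule = 2)$y
    model_loading <- tibble::tibble(time_s = model_times, strain = model_strain)
    model_fun <- function(g) {
      stress_recursive(material_from_g(g, beta, bulk_modulus), model_loading)
    }
  }

  objective <- function(g) sse_objective(model_fun(g), data_fit, spec)

  scale0 <- max(data_fit$stress_pa) / max(hold_strain, 1e-9)
  starts <- fit_starts(start, n_starts, scale0, upper, seed)
  best <- NULL
  history <- list()
  n_eval <- 0L
  for (s in seq_len(nrow(starts))) {
    res <- stats::optim(
      par = starts[s, ], fn = objective, method = "L-BFGS-B",
      lower = rep(0, 4), upper = rep(upper, 4),
      control = list(maxit = 500L, factr = 1e4)
    )
    n_eval <- n_eval + res$counts[1]
    history[[s]] <- tibble::tibble(
      iteration = s, g_inf = res$par[1], g1 = res$par[2], g2 = res$par[3],
      g3 = res$par[4], objective = res$value,
      converged = res$convergence == 0L
    )
    if (is.null(best) || res$value < best$value ||
        (res$value == best$value && sum(res$par) < sum(best$par))) {
      best <- res
    }
  }
  new_fit_result(
    material = material_from_g(best$par, beta, bulk_modulus),
    mode = paste0("analytical_", mode),
    sse = best$value,
    iterations = dplyr::bind_rows(history),
    n_eval = as.integer(n_eval),
    converged = best$convergence == 0L
  )
}

material_from_g <- function(g, beta, bulk_modulus) {
  prony_material(g_inf = g[1], g_terms = g[2:4], beta = beta,
                 bulk_modulus = bulk_modulus)
}

fit_starts <- function(start, n_starts, scale0, upper, seed) {
  if (!is.null(start)) return(matrix(as.numeric(start), nrow = 1L))
  base <- pmin(rep(scale0 / 4, 4), upper / 2)
  extra <- max(0L, n_starts - 1L)
  withr_seed <- function(expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    expr
  }
  rand <- withr_seed(matrix(stats::runif(4L * extra, 0.1, 2), ncol = 4L))
  rbind(base, sweep(rand, 2, base, `*`))
}

new_fit_result <- function(material, mode, sse, iterations, n_eval,
                           converged = TRUE, extra = list()) {
  structure(
    c(list(material = material, mode = mode, sse = sse,
           iterations = iterations, n_eval = n_eval, converged = converged),
      extra),
    class = "fit_result"
  )
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> mode %s, SSE %.6g (%d objective evaluations%s)\n",
              x$mode, x$sse, x$n_eval,
              if (x$converged) "" else "; optimizer did not converge"))
  cat(sprintf("  G_inf = %.4g Pa, G_i = (%s) Pa, G_0 = %.4g Pa\n",
              x$material$g_inf,
              paste(signif(x$material$g_terms, 4), collapse = ", "),
              x$material$g0))
  invisible(x)
}
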