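#' Prony-series linear viscoelastic material
#'
#' Constructs a three-term Prony-series shear relaxation material with a
#' rate-independent (constant) bulk modulus, the standard small-strain
#' linear-viscoelastic model for brain tissue in ramp-and-hold shear tests.
#' The shear relaxation function is
#' \deqn{G(t) = G_\infty + \sum_{i=1}^{3} G_i e^{-\beta_i t},}
#' with fixed decay rates \eqn{\beta_i} spanning three orders of magnitude by
#' default (1, 10, 100 per second) so that both the ~0.1 s loading ramp and
#' the ~4 s hold are covered.
#'
#' @param g_inf Long-term shear modulus \eqn{G_\infty} (Pa), non-negative.
#' @param g_terms Numeric vector of three Prony shear moduli \eqn{G_i} (Pa),
#'   all non-negative.
#' @param beta Decay rates \eqn{\beta_i} (1/s), strictly positive and strictly
#'   increasing. Default `c(1, 10, 100)`.
#' @param bulk_modulus Constant bulk modulus K (Pa). Default 2.1e9, the
#'   water-like value conventionally assumed for brain.
#'
#' @return An object of class `prony_material`: a list with elements
#'   `g_inf`, `g_terms`, `beta`, `bulk_modulus` and the derived instantaneous
#'   modulus `g0 = g_inf + sum(g_terms)`.
#' @examples
#' mat <- prony_material(g_inf = 200, g_terms = c(500, 300, 200))
#' mat$g0                      # 1200 Pa
#' relaxation_modulus(mat, 0)  # equals g0
#' @export
prony_material <- function(g_inf, g_terms, beta = c(1, 10, 100),
                           bulk_modulus = 2.1e9) {
  g_inf <- as.numeric(g_inf)
  g_terms <- as.numeric(g_terms)
  beta <- as.numeric(beta)
  stopifnot(length(g_inf) == 1L, length(g_terms) == length(beta))
  if (g_inf < 0 || any(g_terms < 0)) {
    stop("Shear moduli must be non-negative (relaxation function must be non-increasing).")
  }
  if (any(beta <= 0) || any(diff(beta) <= 0)) {
    stop("Decay rates `beta` must be strictly positive and strictly increasing.")
  }
  if (bulk_modulus <= 0) stop("`bulk_modulus` must be positive.")
  structure(
    list(
      g_inf = g_inf,
      g_terms = g_terms,
      beta = beta,
      bulk_modulus = bulk_modulus,
      g0 = g_inf + sum(g_terms)
    ),
    class = "prony_material"
  )
}

#' @export
print.prony_material <- function(x, ...) {
  cat("<prony_material>\n")
  cat(sprintf("  G_inf: %.6g Pa   G_0: %.6g Pa\n", x$g_inf, x$g0))
  cat(sprintf("  G_i:   %s Pa\n", paste(signif(x$g_terms, 6), collapse = ", ")))
  cat(sprintf("  beta:  %s 1/s\n", paste(x$beta, collapse = ", ")))
  cat(sprintf("  K:     %.3g Pa\n", x$bulk_modulus))
  invisible(x)
}

#' Shear relaxation modulus G(t)
#'
#' Evaluates the Prony-series relaxation function
#' \eqn{G(t) = G_\infty + \sum_i G_i e^{-\beta_i t}}.
#'
#' @param material A [prony_material()].
#' @param t Times (s), non-negative; vectorised.
#' @return Shear modulus (Pa) at each `t`.
#' @export
relaxation_modulus <- function(material, t) {
  stopifnot(inherits(material, "prony_material"))
  t <- as.numeric(t)
  if (any(t < 0)) stop("`t` must be non-negative.")
  material$g_inf +
    colSums(material$g_terms * exp(-outer(material$beta, t)))
}

#' Reduced shear relaxation function
#'
#' Returns the relaxation modulus normalised by the long-term modulus,
#' \eqn{G_r(t) = G(t)/G_\infty}. Note this normalisation uses the long-term
#' (not the instantaneous) modulus, so \eqn{G_r(0) = G_0/G_\infty \ge 1} and
#' \eqn{G_r(\infty) = 1}.
#'
#' @inheritParams relaxation_modulus
#' @param times Times (s), non-negative.
#' @return Dimensionless curve, same length as `times`.
#' @export
reduced_relaxation <- function(material, times) {
  stopifnot(inherits(material, "prony_material"))
  if (material$g_inf <= 0) {
    stop("Reduced relaxation G(t)/G_inf requires g_inf > 0.")
  }
  relaxation_modulus(material, times) / material$g_inf
}
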