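# FE-based identification by successive response-surface methodology (SRSM):
# iteratively sample the FE objective at D-optimally chosen points in a
# shrinking trust region of (G_inf, G1, G2, G3), fit a full quadratic
# surface, and move the region to the surface optimum.

#' SRSM configuration
#'
#' @param n_iterations Number of SRSM iterations (default 5).
#' @param region_frac Initial trust-region half-width as a fraction of the
#'   start values (default 0.4).
#' @param contraction Per-iteration shrink factor of the region half-width
#'   (default 0.65).
#' @param pool_size Size of the seeded uniform candidate pool from which
#'   design points are selected (default 500).
#' @param n_design Design points per iteration, at least 1.5 x the 15
#'   quadratic-basis terms (default 23, including the region centre).
#' @param seed Integer seed for the candidate pool.
#' @return A list of class `srsm_config`.
#' @export
srsm_config <- function(n_iterations = 5L, region_frac = 0.4,
                        contraction = 0.65, pool_size = 500L,
                        n_design = 23L, seed = 1L) {
  if (n_design < ceiling(1.5 * 15)) {
    stop("`n_design` must be at least 1.5 x the 15 quadratic-basis terms (23).")
  }
  structure(list(n_iterations = as.integer(n_iterations),
                 region_frac = region_frac, contraction = contraction,
                 pool_size = as.integer(pool_size),
                 n_design = as.integer(n_design), seed = as.integer(seed)),
            class = "srsm_config")
}

# full quadratic basis in 4 scaled variables: 1, z, z^2, z_i z_j (15 terms)
quad_basis <- function(Z) {
  if (is.null(dim(Z))) Z <- matrix(Z, nrow = 1L)
  cbind(
    1, Z, Z^2,
    Z[, 1] * Z[, 2], Z[, 1] * Z[, 3], Z[, 1] * Z[, 4],
    Z[, 2] * Z[, 3], Z[, 2] * Z[, 4], Z[, 3] * Z[, 4]
  )
}

# greedy D-optimal subset: seed with pivoted-QR rows, then add the candidate
# with maximal prediction leverage f' (F'F)^-1 f until n points are chosen
d_optimal_select <- function(Fc, n) {
  p <- ncol(Fc)
  qrp <- qr(t(Fc), LAPACK = TRUE)
  chosen <- qrp$pivot[seq_len(p)]
  M <- crossprod(Fc[chosen, , drop = FALSE])
  ridge <- 1e-10 * mean(diag(M))
  while (length(chosen) < n) {
    Minv <- solve(M + ridge * diag(p))
    lev <- rowSums((Fc %*% Minv) * Fc)
    lev[chosen] <- -Inf
    pick <- which.max(lev)
    chosen <- c(chosen, pick)
    M <- M + tcrossprod(Fc[pick, ])
  }
  chosen
}

#' FE-based Prony-moduli identification (successive response surfaces)
#'
#' Identifies the four shear coefficients by minimising the SSE between the
#' measured shear-force trace and the FE-predicted reaction force of the
#' specimen model. Each iteration: (i) a box trust region is centred on the
#' current best point; (ii) design points are chosen by greedy D-optimal
#' selection from a seeded uniform candidate pool; (iii) the FE model is
#' solved at every design point and the force-SSE recorded; (iv) a full
#' quadratic response surface is fitted by least squares; (v) the surface is
#' minimised within the region (non-negative moduli enforced through the
#' region bounds) and the minimiser is itself simulated; (vi) the region
#' contracts onto the best simulated point. The returned parameters are the
#' best *simulated* point, never a surface prediction.
#'
#' @param data Measured force trace tibble (`time_s`, `force_n`).
#' @param loading The applied [loading_history()].
#' @param mesh Specimen [build_mesh()].
#' @param start A [prony_material()] used as the initial guess; conventionally
#'   the analytical with-ramp optimum.
#' @param spec An [objective_spec()].
#' @param config An [srsm_config()].
#' @param solver A [solver_config()] used for every FE evaluation.
#' @return A `fit_result` with per-iteration history (`iterations`) and the
#'   total number of FE evaluations (`n_eval`).
#' @export
fit_fe_srsm <- function(data, loading, mesh, start,
                        spec = objective_spec(),
                        config = srsm_config(),
                        solver = solver_config()) {
  stopifnot(inherits(start, "prony_material"), inherits(mesh, "hex_mesh"))
  op <- build_fe_operator(mesh)
  beta <- start$beta
  bulk <- start$bulk_modulus

  evaluate <- function(g) {
    mat <- material_from_g(g, beta, bulk)
    sol <- tryCatch(
      solve_shear(mesh, mat, loading, config = solver, operator = op),
      error = function(e) e
    )
    if (inherits(sol, "error")) return(NA_real_)
    sse_objective(sol$force_trace, data, spec)
  }

  res <- srsm_minimize(evaluate, centre = c(start$g_inf, start$g_terms),
                       config = config)
  new_fit_result(
    material = material_from_g(res$best_g, beta, bulk),
    mode = "fe_based",
    sse = res$best_f,
    iterations = res$history,
    n_eval = res$n_eval,
    converged = TRUE
  )
}

#' Core SRSM loop over an arbitrary objective
#'
#' Iteratively minimises `objective` (a function of a length-4 non-negative
#' parameter vector returning a scalar, `NA` on failure) by D-optimal
#' sampling, quadratic response surfaces and a panning/contracting trust
#' region. Exposed mainly so the surrogate machinery can be exercised against
#' closed-form objectives.
#'
#' @param objective Function of a numeric length-4 vector.
#' @param centre Starting point (also the first region centre).
#' @param config An [srsm_config()].
#' @return List: `best_g`, `best_f`, `history` (tibble), `n_eval`.
#' @export
srsm_minimize <- function(objective, centre, config = srsm_config()) {
  n_eval <- 0L
  evaluate <- function(g) {
    n_eval <<- n_eval + 1L
    objective(g)
  }
  half <- config$region_frac * pmax(centre, 1e-2 * max(centre))
  best_g <- centre
  best_f <- evaluate(centre)
  history <- list()

  set.seed(config$seed)
  for (it in seq_len(config$n_iterations)) {
    lo <- pmax(0, centre - half)
    hi <- centre + half
    # seeded candidate pool in scaled coordinates z in [-1, 1]^4
    Zc <- matrix(stats::runif(4L * config$pool_size, -1, 1), ncol = 4L)
    Fc <- quad_basis(Zc)
    sel <- tryCatch(
      d_optimal_select(Fc, config$n_design - 1L),
      error = function(e) {
        # singular information matrix: enlarge the pool and retry
        Zc <<- rbind(Zc, matrix(stats::runif(8L * config$pool_size, -1, 1),
                                ncol = 4L))
        Fc <<- quad_basis(Zc)
        d_optimal_select(Fc, config$n_design - 1L)
      }
    )
    unscale <- function(z) lo + (z + 1) / 2 * (hi - lo)
    scale_g <- function(g) 2 * (g - lo) / pmax(hi - lo, 1e-12) - 1
    G_design <- t(apply(Zc[sel, , drop = FALSE], 1, unscale))
    G_design <- rbind(centre, G_design)            # centre always evaluated
    f_vals <- apply(G_design, 1, evaluate)
    ok <- is.finite(f_vals)
    if (sum(ok) < 15L) stop("Too many failed objective evaluations to fit a surface.")
    if (any(!ok)) warning(sum(!ok), " design point(s) failed and were dropped.")

    Zd <- t(apply(G_design[ok, , drop = FALSE], 1, scale_g))
    coef <- stats::lsfit(quad_basis(Zd), f_vals[ok], intercept = FALSE)$coefficients
    surf <- function(z) sum(quad_basis(z) * coef)
    opt <- stats::optim(rep(0, 4), surf, method = "L-BFGS-B",
                        lower = rep(-1, 4), upper = rep(1, 4))
    g_surf <- unscale(opt$par)
    f_surf <- evaluate(g_surf)

    G_all <- rbind(G_design[ok, , drop = FALSE], g_surf)
    f_all <- c(f_vals[ok], f_surf)
    i_best <- which.min(f_all)
    if (is.finite(f_all[i_best]) && f_all[i_best] < best_f) {
      best_f <- f_all[i_best]
      best_g <- G_all[i_best, ]
    }
    history[[it]] <- tibble::tibble(
      iteration = it, g_inf = best_g[1], g1 = best_g[2], g2 = best_g[3],
      g3 = best_g[4], objective = best_f, surface_objective = opt$value,
      n_design = sum(ok)
    )
    # pan/shrink: full contraction when the optimum stays at the centre,
    # no contraction (pure pan) when it moves to the region boundary
    move <- pmin(abs(best_g - centre) / pmax(half, 1e-300), 1)
    half <- half * (config$contraction + move * (1 - config$contraction))
    centre <- best_g
  }
  list(best_g = best_g, best_f = best_f,
       history = dplyr::bind_rows(history), n_eval = n_eval)
}
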