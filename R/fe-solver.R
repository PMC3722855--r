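# Quasi-static nearly incompressible linear-viscoelastic FE solver for
# prescribed simple shear of hex-8 specimen meshes.
#
# Discretisation: trilinear hexahedra, 2x2x2 Gauss quadrature, mean-dilatation
# (B-bar) treatment of the volumetric term so the K/G ~ 1e6 near-incompressible
# material does not lock. The deviatoric stress follows the same per-term
# Prony recursion as the 1-D stress update, applied componentwise to the
# deviatoric strain tensor at every Gauss point; the volumetric response is
# elastic (rate-independent bulk modulus).

hex_gauss_points <- function() {
  g <- 1 / sqrt(3)
  xi <- as.matrix(expand.grid(xi = c(-g, g), eta = c(-g, g), zeta = c(-g, g)))
  list(xi = xi, w = rep(1, 8))
}

# natural-coordinate node positions matching the mesh connectivity order:
# bottom quad counter-clockwise, then top quad
hex_node_xi <- function() {
  rbind(
    c(-1, -1, -1), c(1, -1, -1), c(1, 1, -1), c(-1, 1, -1),
    c(-1, -1, 1), c(1, -1, 1), c(1, 1, 1), c(-1, 1, 1)
  )
}

# 8x3 matrix of shape-function gradients wrt natural coordinates
hex_shape_grad <- function(xi) {
  xn <- hex_node_xi()
  out <- matrix(0, 8, 3)
  for (a in 1:8) {
    out[a, 1] <- xn[a, 1] * (1 + xi[2] * xn[a, 2]) * (1 + xi[3] * xn[a, 3]) / 8
    out[a, 2] <- xn[a, 2] * (1 + xi[1] * xn[a, 1]) * (1 + xi[3] * xn[a, 3]) / 8
    out[a, 3] <- xn[a, 3] * (1 + xi[1] * xn[a, 1]) * (1 + xi[2] * xn[a, 2]) / 8
  }
  out
}

# physical shape-function gradients and Jacobian determinants at one natural
# point for all elements: returns list(grad = ne x 8 x 3 array, detJ = ne)
hex_grad_all <- function(mesh, xi) {
  ne <- mesh$n_elements
  dN <- hex_shape_grad(xi)
  J <- array(0, dim = c(ne, 3, 3))
  for (a in 1:8) {
    xa <- mesh$nodes[mesh$elements[, a], , drop = FALSE]
    for (i in 1:3) for (j in 1:3) {
      J[, i, j] <- J[, i, j] + dN[a, i] * xa[, j]
    }
  }
  detJ <- J[, 1, 1] * (J[, 2, 2] * J[, 3, 3] - J[, 2, 3] * J[, 3, 2]) -
    J[, 1, 2] * (J[, 2, 1] * J[, 3, 3] - J[, 2, 3] * J[, 3, 1]) +
    J[, 1, 3] * (J[, 2, 1] * J[, 3, 2] - J[, 2, 2] * J[, 3, 1])
  if (any(detJ <= 0)) stop("Element inversion: non-positive Jacobian determinant.")
  # inverse of J, cofactor form, vectorised over elements
  iJ <- array(0, dim = c(ne, 3, 3))
  iJ[, 1, 1] <- (J[, 2, 2] * J[, 3, 3] - J[, 2, 3] * J[, 3, 2]) / detJ
  iJ[, 1, 2] <- (J[, 1, 3] * J[, 3, 2] - J[, 1, 2] * J[, 3, 3]) / detJ
  iJ[, 1, 3] <- (J[, 1, 2] * J[, 2, 3] - J[, 1, 3] * J[, 2, 2]) / detJ
  iJ[, 2, 1] <- (J[, 2, 3] * J[, 3, 1] - J[, 2, 1] * J[, 3, 3]) / detJ
  iJ[, 2, 2] <- (J[, 1, 1] * J[, 3, 3] - J[, 1, 3] * J[, 3, 1]) / detJ
  iJ[, 2, 3] <- (J[, 1, 3] * J[, 2, 1] - J[, 1, 1] * J[, 2, 3]) / detJ
  iJ[, 3, 1] <- (J[, 2, 1] * J[, 3, 2] - J[, 2, 2] * J[, 3, 1]) / detJ
  iJ[, 3, 2] <- (J[, 1, 2] * J[, 3, 1] - J[, 1, 1] * J[, 3, 2]) / detJ
  iJ[, 3, 3] <- (J[, 1, 1] * J[, 2, 2] - J[, 1, 2] * J[, 2, 1]) / detJ
  # dN/dx_j = sum_i (J^-1)_{ji} dN/dxi_i  with J_{ij} = dx_j/dxi_i
  grad <- array(0, dim = c(ne, 8, 3))
  for (a in 1:8) for (j in 1:3) {
    grad[, a, j] <- iJ[, j, 1] * dN[a, 1] + iJ[, j, 2] * dN[a, 2] +
      iJ[, j, 3] * dN[a, 3]
  }
  list(grad = grad, detJ = detJ)
}

# strain-displacement triplets for one natural point over all elements.
# Rows are Voigt components (exx, eyy, ezz, gxy, gyz, gxz; engineering shear)
# at consecutive row blocks row0 + 6*(e-1) + comp.
strain_triplets <- function(mesh, grad, row_stride, row_offset) {
  ne <- mesh$n_elements
  is <- js <- xs <- vector("list", 8L * 9L)
  k <- 0L
  erow <- row_stride * (seq_len(ne) - 1L) + row_offset
  for (a in 1:8) {
    nd <- mesh$elements[, a]
    dofx <- 3L * (nd - 1L) + 1L
    dofy <- 3L * (nd - 1L) + 2L
    dofz <- 3L * (nd - 1L) + 3L
    gx <- grad[, a, 1]; gy <- grad[, a, 2]; gz <- grad[, a, 3]
    add <- function(r, c, v) {
      k <<- k + 1L
      is[[k]] <<- erow + r; js[[k]] <<- c; xs[[k]] <<- v
    }
    add(0L, dofx, gx)           # exx
    add(1L, dofy, gy)           # eyy
    add(2L, dofz, gz)           # ezz
    add(3L, dofx, gy); add(3L, dofy, gx)  # gxy
    add(4L, dofy, gz); add(4L, dofz, gy)  # gyz
    add(5L, dofx, gz); add(5L, dofz, gx)  # gxz
  }
  list(i = unlist(is), j = unlist(js), x = unlist(xs))
}

# deviatoric stress for unit shear modulus from Voigt strain rows (6 x n):
# normal rows 2*(e - tr/3), shear rows tau = gamma (engineering shear)
dev_stress_unit <- function(eps6) {
  tr <- eps6[1, ] + eps6[2, ] + eps6[3, ]
  out <- eps6
  out[1:3, ] <- 2 * (sweep(eps6[1:3, , drop = FALSE], 2, tr / 3))
  out
}

#' Build the reusable FE operator for a mesh
#'
#' Assembles, once per mesh, everything the time stepper needs: the global
#' strain operator at all Gauss points, quadrature weights, unit-modulus
#' deviatoric and volumetric stiffness matrices (B-bar / mean dilatation),
#' centroid strain operator, DOF partitions for the shear boundary
#' conditions, and element volumes. Reusing the operator across repeated
#' [solve_shear()] calls on the same mesh (as the FE-based identification
#' does) skips re-assembly.
#'
#' @param mesh A [build_mesh()] result.
#' @return An object of class `fe_operator` (opaque list).
#' @export
build_fe_operator <- function(mesh) {
  ne <- mesh$n_elements
  nn <- nrow(mesh$nodes)
  ndof <- 3L * nn
  gp <- hex_gauss_points()
  ngp <- 8L * ne

  trip_i <- trip_j <- trip_x <- vector("list", 8L)
  wdet <- matrix(0, nrow = ne, ncol = 8L)          # w * detJ per (element, gp)
  bvol_i <- bvol_j <- bvol_x <- vector("list", 8L)
  for (g in 1:8) {
    ga <- hex_grad_all(mesh, gp$xi[g, ])
    wdet[, g] <- gp$w[g] * ga$detJ
    # strain rows for this gp: row block 6*8*(e-1) + 6*(g-1) + comp
    tr <- strain_triplets(mesh, ga$grad, 48L, 6L * (g - 1L) + 1L)
    trip_i[[g]] <- tr$i; trip_j[[g]] <- tr$j; trip_x[[g]] <- tr$x
    # volumetric b-vector accumulation: sum_g w detJ * dN_a/dx_i
    bi <- bj <- bx <- vector("list", 8L)
    for (a in 1:8) {
      nd <- mesh$elements[, a]
      bi[[a]] <- rep(seq_len(ne), 3L)
      bj[[a]] <- c(3L * (nd - 1L) + 1L, 3L * (nd - 1L) + 2L, 3L * (nd - 1L) + 3L)
      bx[[a]] <- c(ga$grad[, a, 1], ga$grad[, a, 2], ga$grad[, a, 3]) *
        rep(wdet[, g], 3L)
    }
    bvol_i[[g]] <- unlist(bi); bvol_j[[g]] <- unlist(bj); bvol_x[[g]] <- unlist(bx)
  }
  Ed <- Matrix::sparseMatrix(
    i = unlist(trip_i), j = unlist(trip_j), x = unlist(trip_x),
    dims = c(6L * ngp, ndof)
  )
  Ve <- rowSums(wdet)
  Bvol <- Matrix::sparseMatrix(
    i = unlist(bvol_i), j = unlist(bvol_j), x = unlist(bvol_x) / Ve[unlist(bvol_i)],
    dims = c(ne, ndof)
  )

  # unit-modulus deviatoric stiffness: Kd = Ed' * blockdiag(w detJ * D1) * Ed
  wvec <- as.vector(t(wdet))                        # gp-major within element
  w6 <- rep(wvec, each = 6L)
  Dd <- dev_unit_block(ngp, wvec)
  Kd <- Matrix::forceSymmetric(Matrix::t(Ed) %*% (Dd %*% Ed))
  Kv <- Matrix::forceSymmetric(Matrix::t(Bvol) %*% (Ve * Bvol))

  # centroid strain operator (one natural point xi = 0 per element)
  gc <- hex_grad_all(mesh, c(0, 0, 0))
  trc <- strain_triplets(mesh, gc$grad, 6L, 1L)
  Ecent <- Matrix::sparseMatrix(i = trc$i, j = trc$j, x = trc$x,
                                dims = c(6L * ne, ndof))

  # boundary conditions for prescribed simple shear
  bot <- mesh$bottom_face_nodes
  top <- mesh$top_face_nodes
  fixed <- c(3L * (bot - 1L) + 1L, 3L * (bot - 1L) + 2L, 3L * (bot - 1L) + 3L,
             3L * (top - 1L) + 2L, 3L * (top - 1L) + 3L)
  driven <- 3L * (top - 1L) + 1L                    # prescribed x displacement
  pres <- c(fixed, driven)
  free <- setdiff(seq_len(ndof), pres)
  bottom_x <- 3L * (bot - 1L) + 1L

  structure(list(
    mesh = mesh, ndof = ndof, ngp = ngp, Ed = Ed, w6 = w6, wvec = wvec,
    Kd = Kd, Kv = Kv, Bvol = Bvol, Ve = Ve, Ecent = Ecent,
    free = free, pres = pres, driven = driven, bottom_x = bottom_x,
    Kd_ff = Kd[free, free], Kd_fp = Kd[free, pres],
    Kv_ff = Kv[free, free], Kv_fp = Kv[free, pres],
    Kd_bot = Kd[bottom_x, ], Kv_bot = Kv[bottom_x, ]
  ), class = "fe_operator")
}

# sparse block-diagonal unit-modulus deviatoric elasticity, scaled per gp
dev_unit_block <- function(ngp, wvec) {
  # normal block: 2*(I - 11'/3): diag 4/3, off-diag -2/3; shear diag 1
  base_i <- c(rep(1:3, each = 3L), 4L, 5L, 6L)
  base_j <- c(rep(1:3, times = 3L), 4L, 5L, 6L)
  base_x <- c(
    4 / 3, -2 / 3, -2 / 3,
    -2 / 3, 4 / 3, -2 / 3,
    -2 / 3, -2 / 3, 4 / 3,
    1, 1, 1
  )
  off <- 6L * (seq_len(ngp) - 1L)
  Matrix::sparseMatrix(
    i = rep(off, each = length(base_i)) + rep(base_i, ngp),
    j = rep(off, each = length(base_j)) + rep(base_j, ngp),
    x = rep(wvec, each = length(base_x)) * rep(base_x, ngp),
    dims = c(6L * ngp, 6L * ngp)
  )
}

# effective shear modulus of one implicit step of length dt (constant strain
# rate within the step): G_eff = G_inf + sum Gi (1 - exp(-bi dt)) / (bi dt)
effective_shear_modulus <- function(material, dt) {
  x <- exp(-material$beta * dt)
  material$g_inf + sum(material$g_terms * (1 - x) / (material$beta * dt))
}

#' Solver configuration
#'
#' Time-stepping controls for [solve_shear()]. The ramp is stepped uniformly
#' and the hold on a logarithmic grid, mirroring the log-time comparison grid
#' used for fitting.
#'
#' @param n_ramp_steps Uniform steps across the strain ramp (default 50).
#' @param n_hold_steps Log-spaced steps across the hold (default 150).
#' @param store_displacements Keep the full nodal displacement history
#'   (matrix, one column per step)? Default `FALSE`; the displacement field
#'   at peak strain is always kept.
#' @return A list of class `solver_config`.
#' @export
solver_config <- function(n_ramp_steps = 50L, n_hold_steps = 150L,
                          store_displacements = FALSE) {
  stopifnot(n_ramp_steps >= 1L, n_hold_steps >= 1L)
  structure(list(n_ramp_steps = as.integer(n_ramp_steps),
                 n_hold_steps = as.integer(n_hold_steps),
                 store_displacements = store_displacements),
            class = "solver_config")
}

# solver time grid: uniform over the ramp, then geometrically growing step
# blocks over the hold (log-like coverage). Constant step size within each
# block keeps the number of distinct step lengths -- and hence matrix
# factorisations -- small.
solver_times <- function(ramp_time, total_time, config,
                         n_blocks = 12L, ratio = 1.5) {
  ramp <- seq(0, ramp_time, length.out = config$n_ramp_steps + 1L)
  span <- total_time - ramp_time
  nb <- min(n_blocks, config$n_hold_steps)
  m <- ceiling(config$n_hold_steps / nb)
  dts <- rep(ratio^(seq_len(nb) - 1L), each = m)
  dts <- dts * (span / sum(dts))
  c(ramp, ramp_time + cumsum(dts))
}

#' Quasi-static FE solution of a prescribed simple-shear test
#'
#' Steps the specimen mesh through the loading history: the bottom face is
#' fully fixed, the top face is fixed in y and z with prescribed
#' x-displacement `strain(t) * height`, and each increment solves the linear
#' system with the step-effective shear modulus of the Prony recursion. The
#' reaction force is the x-resultant transmitted to the bottom plate
#' (positive during loading).
#'
#' @param mesh A [build_mesh()] result.
#' @param material A [prony_material()].
#' @param loading A [loading_history()]; it is linearly resampled onto the
#'   solver time grid.
#' @param config A [solver_config()].
#' @param operator Optional pre-built [build_fe_operator()] for `mesh`
#'   (reused across repeated solves in fitting loops).
#' @return An object of class `fe_solution`: list with `force_trace`
#'   (tibble `time_s`, `force_n`), `element_strains_at_peak` (engineering
#'   shear strain, 2 eps_xz, at element centroids at peak displacement),
#'   `times`, `peak_time`, `volume_change_peak` (m^3), `u_peak`, and
#'   optionally `displacements`.
#' @export
solve_shear <- function(mesh, material, loading, config = solver_config(),
                        operator = NULL) {
  stopifnot(inherits(mesh, "hex_mesh"), inherits(material, "prony_material"))
  if (is.null(operator)) operator <- build_fe_operator(mesh)
  op <- operator
  ramp_time <- attr(loading, "ramp_time")
  if (is.null(ramp_time)) ramp_time <- loading$time_s[which.max(loading$strain)]
  times <- solver_times(ramp_time, max(loading$time_s), config)
  gamma <- stats::approx(loading$time_s, loading$strain, xout = times,
                         rule = 2)$y
  height <- mesh$geometry$height
  K <- material$bulk_modulus
  nb <- length(material$beta)
  ngp <- op$ngp
  nfree <- length(op$free)

  eps_prev <- matrix(0, nrow = 6L, ncol = ngp)
  s_terms <- vector("list", nb)
  for (i in seq_len(nb)) s_terms[[i]] <- matrix(0, nrow = 6L, ncol = ngp)

  nsteps <- length(times) - 1L
  force <- numeric(length(times))
  u <- numeric(op$ndof)
  peak_idx <- which.max(gamma)[1]
  u_peak <- NULL
  disp_hist <- if (config$store_displacements) {
    matrix(0, nrow = op$ndof, ncol = length(times))
  } else NULL

  u_pres_template <- numeric(length(op$pres))
  n_fixed <- length(op$pres) - length(op$driven)

  # one factorisation (and constraint-coupling block) per distinct step size
  fac_cache <- new.env(parent = emptyenv())
  chol_symb <- NULL
  step_ops <- function(dt, g_eff) {
    key <- sprintf("%.15g", dt)
    if (!is.null(fac_cache[[key]])) return(fac_cache[[key]])
    A_ff <- Matrix::forceSymmetric(g_eff * op$Kd_ff + K * op$Kv_ff)
    if (is.null(chol_symb)) {
      ch <- Matrix::Cholesky(A_ff, LDL = FALSE)
      chol_symb <<- ch
    } else {
      ch <- update(chol_symb, A_ff)  # reuse symbolic factorisation
    }
    val <- list(chol = ch, A_fp = g_eff * op$Kd_fp + K * op$Kv_fp)
    fac_cache[[key]] <- val
    val
  }

  for (k in seq_len(nsteps)) {
    dt <- times[k + 1L] - times[k]
    if (dt <= 0) stop("Non-positive time step in solver grid.")
    g_eff <- effective_shear_modulus(material, dt)
    x_decay <- exp(-material$beta * dt)

    # history stress (independent of the unknown step displacement):
    # r = (G_inf - G_eff) * D1 eps_prev + sum_i x_i s_i
    r <- (material$g_inf - g_eff) * dev_stress_unit(eps_prev)
    for (i in seq_len(nb)) r <- r + x_decay[i] * s_terms[[i]]
    f_hist <- Matrix::crossprod(op$Ed, op$w6 * as.vector(r))

    u_pres <- u_pres_template
    u_pres[n_fixed + seq_along(op$driven)] <- gamma[k + 1L] * height

    so <- step_ops(dt, g_eff)
    rhs <- -f_hist[op$free] - so$A_fp %*% u_pres
    u_free <- as.numeric(Matrix::solve(so$chol, rhs))
    u[op$free] <- u_free
    u[op$pres] <- u_pres

    eps_new <- matrix(as.numeric(op$Ed %*% u), nrow = 6L)
    d_eps <- eps_new - eps_prev
    ds_unit <- dev_stress_unit(d_eps)
    for (i in seq_len(nb)) {
      s_terms[[i]] <- x_decay[i] * s_terms[[i]] +
        ((1 - x_decay[i]) / (material$beta[i] * dt)) *
          material$g_terms[i] * ds_unit
    }
    eps_prev <- eps_new

    # bottom-plate reaction: internal-force rows at the bottom x-DOFs are
    # (g_eff Kd + K Kv) u + f_hist restricted to those rows
    force[k + 1L] <- -sum(
      g_eff * as.numeric(op$Kd_bot %*% u) + K * as.numeric(op$Kv_bot %*% u) +
        f_hist[op$bottom_x]
    )

    if (k + 1L == peak_idx) u_peak <- u
    if (!is.null(disp_hist)) disp_hist[, k + 1L] <- u
  }
  if (is.null(u_peak)) u_peak <- u  # peak at final step (monotone loading)

  cent <- matrix(as.numeric(op$Ecent %*% u_peak), nrow = 6L)
  strains_peak <- cent[6L, ]                        # engineering 2*eps_xz
  vol_change <- sum(op$Ve * as.numeric(op$Bvol %*% u_peak))

  structure(list(
    force_trace = new_force_trace(times, force),
    element_strains_at_peak = strains_peak,
    element_strain_tensors_at_peak = t(cent),
    times = times,
    peak_time = times[peak_idx],
    volume_change_peak = vol_change,
    u_peak = u_peak,
    displacements = disp_hist,
    mesh = mesh
  ), class = "fe_solution")
}

#' @export
print.fe_solution <- function(x, ...) {
  cat(sprintf(
    "<fe_solution> %d steps, peak force %.4g N at t = %.4g s, %d elements\n",
    nrow(x$force_trace) - 1L, max(x$force_trace$force_n), x$peak_time,
    x$mesh$n_elements
  ))
  invisible(x)
}

#' Element shear-strain census at peak displacement
#'
#' Bins the per-element centroid engineering shear strain (2 eps_xz at peak
#' applied displacement) and reports counts and fractions per bin. Used to
#' quantify how non-uniform the strain field of a bonded cylindrical specimen
#' is compared with the uniform-strain assumption of the analytical fits.
#'
#' @param solution A [solve_shear()] result.
#' @param bin_edges Increasing strain bin edges; values outside the range are
#'   clipped into the end bins when `clip = TRUE` (default).
#' @param clip Clip out-of-range strains into the end bins?
#' @return A tibble with `bin` (label), `lower`, `upper`, `count`,
#'   `fraction`; fractions sum to 1 and counts to the element count.
#' @export
strain_census <- function(solution, bin_edges = c(0, 0.45, 0.50, Inf),
                          clip = TRUE) {
  stopifnot(inherits(solution, "fe_solution"))
  bin_edges <- sort(as.numeric(bin_edges))
  if (length(bin_edges) < 2L) stop("Need at least two bin edges.")
  s <- abs(solution$element_strains_at_peak)
  if (clip) {
    s <- pmin(pmax(s, bin_edges[1]), bin_edges[length(bin_edges)] * (1 - 1e-12))
  }
  idx <- cut(s, breaks = bin_edges, include.lowest = TRUE, right = FALSE)
  counts <- as.integer(table(idx))
  tibble::tibble(
    bin = levels(idx),
    lower = bin_edges[-length(bin_edges)],
    upper = bin_edges[-1],
    count = counts,
    fraction = counts / length(s)
  )
}
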