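# Study pipeline: orchestrates the four numerical experiments on a synthetic
# specimen set and collects their tables into a study_report —
# (1) fit-mode comparison (no-ramp / with-ramp / FE-based),
# (2) 1-D vs 3-D consistency, (3) mesh convergence, (4) shape and height
# sensitivity — plus the strain census and averaged moduli / reduced
# relaxation summaries.

#' Fit-mode comparison on a synthetic specimen set
#'
#' For every specimen: fits the analytical model with and without the ramp to
#' the stress-converted trace, runs the FE-based SRSM identification started
#' from the with-ramp optimum, then re-simulates the specimen FE model under
#' each fitted material and records peak-force and relaxation errors against
#' the (synthetic) data.
#'
#' @param set A [generate_study_set()] result (fe engine).
#' @param spec An [objective_spec()].
#' @param srsm An [srsm_config()].
#' @param solver A [solver_config()]; use the same stepping the set was
#'   generated with so model/data grids agree.
#' @param modes Which fit modes to run.
#' @return A list with `fits` (nested list, per specimen per mode),
#'   `comparison` (tibble: specimen, mode, moduli, SSE, peak-force error,
#'   relaxation SSE), `moduli_summary` (per-mode averages).
#' @export
run_mode_comparison <- function(set, spec = objective_spec(),
                                srsm = srsm_config(),
                                solver = solver_config(),
                                modes = c("analytical_no_ramp",
                                          "analytical_with_ramp",
                                          "fe_based")) {
  stopifnot(inherits(set, "specimen_set"))
  if (is.null(set[[1]]$mesh)) {
    stop("`run_mode_comparison()` needs an fe-engine specimen set (meshes present).")
  }
  rows <- list()
  fits <- list()
  for (k in seq_along(set)) {
    sp <- set[[k]]
    stress_data <- force_to_stress(sp$trace, sp$geometry)
    fit_wr <- fit_analytical(stress_data, sp$loading, mode = "with_ramp",
                             spec = spec)
    fit_nr <- fit_analytical(stress_data, sp$loading, mode = "no_ramp",
                             spec = spec)
    spec_fits <- list(analytical_with_ramp = fit_wr,
                      analytical_no_ramp = fit_nr)
    if ("fe_based" %in% modes) {
      spec_fits$fe_based <- fit_fe_srsm(sp$trace, sp$loading, sp$mesh,
                                        start = fit_wr$material,
                                        spec = spec, config = srsm,
                                        solver = solver)
    }
    fits[[k]] <- spec_fits

    op <- build_fe_operator(sp$mesh)
    data_peak <- max(sp$trace$force_n)
    for (mode in intersect(modes, names(spec_fits))) {
      f <- spec_fits[[mode]]
      sol <- solve_shear(sp$mesh, f$material, sp$loading, config = solver,
                         operator = op)
      errs <- resimulation_errors(sol$force_trace, sp$trace,
                                  attr(sp$loading, "ramp_time"), spec)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        specimen = k, mode = mode,
        g_inf = f$material$g_inf, g0 = f$material$g0,
        fit_sse = f$sse, n_eval = f$n_eval,
        peak_force_error = errs$peak_error,
        relaxation_sse = errs$relax_sse
      )
    }
  }
  comparison <- dplyr::bind_rows(rows)
  moduli_summary <- comparison |>
    dplyr::group_by(.data$mode) |>
    dplyr::summarise(
      mean_g_inf = mean(.data$g_inf), mean_g0 = mean(.data$g0),
      mean_peak_force_error = mean(.data$peak_force_error),
      .groups = "drop"
    )
  list(fits = fits, comparison = comparison, moduli_summary = moduli_summary)
}

# peak error (signed, relative to data peak) and hold-phase log-time SSE
resimulation_errors <- function(model_trace, data_trace, ramp_time, spec) {
  peak_model <- max(model_trace$force_n)
  peak_data <- max(data_trace$force_n)
  relax_spec <- objective_spec(n_points = spec$n_points,
                               t_min = max(ramp_time, spec$t_min))
  list(
    peak_error = (peak_model - peak_data) / peak_data,
    relax_sse = sse_objective(model_trace, data_trace, relax_spec)
  )
}

#' Mesh convergence of the reaction-force trace
#'
#' Runs the FE model at several refinement levels of the same geometry under
#' identical material and loading, and reports each level's maximum pointwise
#' force deviation from the finest level, normalised by the finest level's
#' peak force.
#'
#' @param geometry A [specimen_geometry()].
#' @param material A [prony_material()].
#' @param loading A [loading_history()].
#' @param levels Refinement levels: character names (see
#'   [mesh_refinement_levels()]) or a list of `c(nx, ny, nr, nz)` vectors;
#'   ordered coarse to fine, at least 3.
#' @param solver A [solver_config()].
#' @return Tibble: `level`, `n_elements`, `max_deviation_pct` (vs the finest
#'   level; the finest row is 0 by construction).
#' @export
run_convergence <- function(geometry, material, loading,
                            levels = names(mesh_refinement_levels()),
                            solver = solver_config()) {
  if (length(levels) < 3L) stop("Need at least 3 refinement levels.")
  sols <- list()
  nel <- integer(length(levels))
  for (i in seq_along(levels)) {
    lev <- if (is.list(levels)) levels[[i]] else levels[i]
    mesh <- build_mesh(geometry, refinement = lev)
    nel[i] <- mesh$n_elements
    sols[[i]] <- solve_shear(mesh, material, loading, config = solver)
  }
  ord <- order(nel)
  finest <- sols[[ord[length(ord)]]]$force_trace$force_n
  peak <- max(abs(finest))
  dev_pct <- vapply(sols, function(s) {
    100 * max(abs(s$force_trace$force_n - finest)) / peak
  }, numeric(1))
  tibble::tibble(
    level = if (is.list(levels)) paste0("level", seq_along(levels)) else levels,
    n_elements = nel,
    max_deviation_pct = dev_pct
  )
}

#' Specimen shape and height sensitivity of the peak shear force
#'
#' Re-simulates the specimen FE model with a fitted material over a grid of
#' height factors and cross-section shapes (cube side matched to the cylinder
#' area). The prescribed displacement always corresponds to the same nominal
#' strain (it scales with the current height), and peak forces are reported
#' normalised by the reference data peak.
#'
#' @param material The fitted [prony_material()] (conventionally the
#'   analytical with-ramp optimum).
#' @param geometry Base cylinder [specimen_geometry()].
#' @param loading A [loading_history()].
#' @param data_peak Reference peak force (N) for normalisation (the test or
#'   synthetic-data peak of the factor-1 cylinder).
#' @param height_factors Height multipliers (default `c(1, 0.9, 0.8, 0.7)`).
#' @param shapes Shapes to sweep.
#' @param solver A [solver_config()].
#' @param cylinder_refinement,cube_refinement Mesh refinements passed to
#'   [build_mesh()] for the two shapes.
#' @return Tibble: `shape`, `height_factor`, `peak_force_n`, `peak_ratio`
#'   (peak / `data_peak`), `peak_error` (`peak_ratio - 1`).
#' @export
run_sensitivity <- function(material, geometry, loading, data_peak,
                            height_factors = c(1, 0.9, 0.8, 0.7),
                            shapes = c("cylinder", "cube"),
                            solver = solver_config(),
                            cylinder_refinement = NULL,
                            cube_refinement = NULL) {
  stopifnot(inherits(geometry, "specimen_geometry"), geometry$shape == "cylinder")
  rows <- list()
  for (shape in shapes) {
    for (hf in height_factors) {
      geo <- if (shape == "cylinder") {
        specimen_geometry("cylinder", height = geometry$height * hf,
                          diameter = geometry$diameter)
      } else {
        specimen_geometry("cube", height = geometry$height * hf,
                          diameter = geometry$diameter)
      }
      mesh <- build_mesh(geo, refinement = if (shape == "cylinder") {
        cylinder_refinement
      } else {
        cube_refinement
      })
      sol <- solve_shear(mesh, material, loading, config = solver)
      pk <- max(sol$force_trace$force_n)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        shape = shape, height_factor = hf, n_elements = mesh$n_elements,
        peak_force_n = pk, peak_ratio = pk / data_peak,
        peak_error = pk / data_peak - 1
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Assemble a study report
#'
#' Collects the study tables into a single `study_report` object carrying a
#' hash of the run configuration. All fields are optional; [report()] writes
#' whatever is present.
#'
#' @param mode_comparison,moduli_summary,relaxation_curves,census,convergence,
#'   sensitivity Tibbles from the respective study steps (or `NULL`).
#' @param config Arbitrary run-configuration list; hashed into `config_hash`.
#' @return An object of class `study_report`.
#' @export
study_report <- function(mode_comparison = NULL, moduli_summary = NULL,
                         relaxation_curves = NULL, census = NULL,
                         convergence = NULL, sensitivity = NULL,
                         config = list()) {
  structure(list(
    mode_comparison = mode_comparison,
    moduli_summary = moduli_summary,
    relaxation_curves = relaxation_curves,
    census = census,
    convergence = convergence,
    sensitivity = sensitivity,
    config_hash = rlang::hash(config)
  ), class = "study_report")
}

#' Average reduced relaxation curves by fit mode
#'
#' @param fits Nested fit list from [run_mode_comparison()].
#' @param times Evaluation times (s).
#' @return Tibble: `mode`, `time_s`, `g_reduced` (mean over specimens of
#'   G(t)/G_inf).
#' @export
relaxation_curves <- function(fits, times = exp(seq(log(1e-3), log(4),
                                                    length.out = 100))) {
  rows <- list()
  for (k in seq_along(fits)) {
    for (mode_k in names(fits[[k]])) {
      gr <- reduced_relaxation(fits[[k]][[mode_k]]$material, times)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        specimen = k, mode = mode_k, time_s = times, g_reduced = gr
      )
    }
  }
  dplyr::bind_rows(rows) |>
    dplyr::group_by(.data$mode, .data$time_s) |>
    dplyr::summarise(g_reduced = mean(.data$g_reduced), .groups = "drop")
}

#' Write a study report to disk
#'
#' Writes one CSV per present table, a single JSON summary
#' (`study_report.json`) that round-trips through [read_study_report()], and
#' qualitative plots (force-trace style comparisons, moduli bars, reduced
#' relaxation curves, strain histogram) as PDF files.
#'
#' @param study A [study_report()].
#' @param outdir Output directory (created if missing).
#' @param plots Write plot files as well?
#' @return Invisibly, the paths written.
#' @export
report <- function(study, outdir, plots = TRUE) {
  stopifnot(inherits(study, "study_report"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  tables <- c("mode_comparison", "moduli_summary", "relaxation_curves",
              "census", "convergence", "sensitivity")
  for (tb in tables) {
    p <- file.path(outdir, paste0(tb, ".csv"))
    df <- study[[tb]]
    if (is.null(df)) df <- tibble::tibble()
    readr::write_csv(df, p)
    paths <- c(paths, p)
  }
  jp <- file.path(outdir, "study_report.json")
  ser <- lapply(study[tables], function(df) if (is.null(df)) NULL else df)
  jsonlite::write_json(list(tables = ser, config_hash = study$config_hash),
                       jp, dataframe = "columns", auto_unbox = TRUE,
                       digits = NA, null = "null")
  paths <- c(paths, jp)
  if (plots) {
    if (!is.null(study$moduli_summary)) {
      p <- file.path(outdir, "moduli_by_mode.pdf")
      ggplot2::ggsave(p, plot_moduli(study$moduli_summary),
                      width = 6, height = 4)
      paths <- c(paths, p)
    }
    if (!is.null(study$relaxation_curves)) {
      p <- file.path(outdir, "reduced_relaxation.pdf")
      ggplot2::ggsave(p, plot_relaxation(study$relaxation_curves),
                      width = 6, height = 4)
      paths <- c(paths, p)
    }
    if (!is.null(study$census)) {
      p <- file.path(outdir, "strain_census.pdf")
      ggplot2::ggsave(p, plot_census(study$census), width = 6, height = 4)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}

#' Read back a study report written by [report()]
#'
#' @param path Path to `study_report.json` (or the directory containing it).
#' @return A `study_report` object equal (up to numeric round-trip) to the
#'   one written.
#' @export
read_study_report <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "study_report.json")
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_tb <- function(x) {
    if (is.null(x) || length(x) == 0L) NULL else tibble::as_tibble(x)
  }
  out <- structure(list(
    mode_comparison = as_tb(raw$tables$mode_comparison),
    moduli_summary = as_tb(raw$tables$moduli_summary),
    relaxation_curves = as_tb(raw$tables$relaxation_curves),
    census = as_tb(raw$tables$census),
    convergence = as_tb(raw$tables$convergence),
    sensitivity = as_tb(raw$tables$sensitivity),
    config_hash = raw$config_hash
  ), class = "study_report")
  out
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>\n")
  for (tb in c("mode_comparison", "moduli_summary", "relaxation_curves",
               "census", "convergence", "sensitivity")) {
    df <- x[[tb]]
    cat(sprintf("  %s: %s\n", tb,
                if (is.null(df)) "absent" else sprintf("%d rows", nrow(df))))
  }
  cat("  config hash:", x$config_hash, "\n")
  invisible(x)
}
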