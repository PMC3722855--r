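# Synthetic specimen generator: stands in for the (non-public) cadaveric
# ramp-and-hold shear tests. Generates specimen geometries with realistic
# inter-specimen spread, ramp-and-hold loadings, and force traces from known
# ground-truth materials via either the 1-D recursion or the FE model, with
# optional measurement noise (white noise on the hold, damped-sinusoid
# inertial bursts at the ramp ends).

#' Canonical ramp-and-hold loading
#'
#' Linear ramp to `hold_strain` over `ramp_time`, then constant hold, sampled
#' uniformly. Defaults reproduce the test protocol: 50 percent engineering
#' shear strain reached in 0.1 s, total duration 4 s.
#'
#' @param ramp_time Ramp duration (s, default 0.1).
#' @param hold_strain Held engineering shear strain (default 0.5).
#' @param total_time Total test duration (s, default 4).
#' @param sample_rate Sampling rate (Hz, default 1000).
#' @return A [loading_history()].
#' @export
make_loading <- function(ramp_time = 0.1, hold_strain = 0.5, total_time = 4,
                         sample_rate = 1000) {
  if (ramp_time >= total_time) stop("`ramp_time` must be less than `total_time`.")
  time <- seq(0, total_time, by = 1 / sample_rate)
  if (max(time) < total_time) time <- c(time, total_time)
  # make sure the ramp end is a sample so the hold level is hit exactly
  if (!any(abs(time - ramp_time) < 1e-12)) {
    time <- sort(c(time, ramp_time))
  }
  strain <- ifelse(time < ramp_time, hold_strain * time / ramp_time, hold_strain)
  loading_history(time, strain, ramp_time = ramp_time, hold_strain = hold_strain)
}

#' Measurement noise model for synthetic force traces
#'
#' White noise during the hold plus exponentially damped sinusoid bursts at
#' the start and end of the ramp, emulating the inertial ringing seen in real
#' step-and-hold tests. All amplitudes zero gives a noise-free trace.
#'
#' @param hold_noise_sd White-noise standard deviation (N) applied after the
#'   ramp.
#' @param burst_amplitude Initial amplitude (N) of each ringing burst.
#' @param burst_frequency Burst frequency (Hz, default 150).
#' @param burst_decay Burst decay rate (1/s, default 50).
#' @return A list of class `noise_model`.
#' @export
noise_model <- function(hold_noise_sd = 0, burst_amplitude = 0,
                        burst_frequency = 150, burst_decay = 50) {
  if (hold_noise_sd < 0 || burst_amplitude < 0 || burst_frequency < 0 ||
      burst_decay < 0) {
    stop("Noise parameters must be non-negative.")
  }
  structure(list(hold_noise_sd = hold_noise_sd,
                 burst_amplitude = burst_amplitude,
                 burst_frequency = burst_frequency,
                 burst_decay = burst_decay),
            class = "noise_model")
}

apply_noise <- function(force, time, ramp_time, noise, seed) {
  if (noise$hold_noise_sd == 0 && noise$burst_amplitude == 0) return(force)
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  out <- force
  if (noise$hold_noise_sd > 0) {
    hold <- time > ramp_time
    out[hold] <- out[hold] + stats::rnorm(sum(hold), 0, noise$hold_noise_sd)
  }
  if (noise$burst_amplitude > 0) {
    for (t0 in c(0, ramp_time)) {
      dt <- time - t0
      on_t <- dt >= 0
      phase <- stats::runif(1, 0, 2 * pi)
      out[on_t] <- out[on_t] + noise$burst_amplitude *
        exp(-noise$burst_decay * dt[on_t]) *
        sin(2 * pi * noise$burst_frequency * dt[on_t] + phase)
    }
  }
  out
}

#' Generate one synthetic specimen force trace
#'
#' Noise-free force from the FE model (`engine = "fe"`) or from the 1-D
#' recursion times the cross-sectional area (`engine = "analytical"`), plus
#' the requested measurement noise. The ground-truth material travels with
#' the trace as an attribute, for recovery scoring only; fitting code never
#' reads it.
#'
#' @param material Ground-truth [prony_material()].
#' @param geometry [specimen_geometry()].
#' @param loading [loading_history()].
#' @param noise A [noise_model()].
#' @param engine `"analytical"` or `"fe"`.
#' @param seed Integer seed (used only by the noise).
#' @param mesh Optional pre-built mesh (fe engine); built from `geometry`
#'   otherwise.
#' @param solver [solver_config()] for the fe engine.
#' @return A force trace tibble with attributes `ground_truth` (material) and
#'   `geometry`.
#' @export
generate_specimen_trace <- function(material, geometry, loading,
                                    noise = noise_model(),
                                    engine = c("analytical", "fe"),
                                    seed = 1L, mesh = NULL,
                                    solver = solver_config()) {
  engine <- match.arg(engine)
  ramp_time <- attr(loading, "ramp_time")
  if (engine == "analytical") {
    stress <- stress_recursive(material, loading)
    trace <- new_force_trace(stress$time_s, stress$stress_pa * geometry$area)
  } else {
    if (is.null(mesh)) mesh <- build_mesh(geometry)
    sol <- solve_shear(mesh, material, loading, config = solver)
    trace <- sol$force_trace
  }
  trace$force_n <- apply_noise(trace$force_n, trace$time_s, ramp_time, noise,
                               seed)
  attr(trace, "ground_truth") <- material
  attr(trace, "geometry") <- geometry
  trace
}

#' Synthetic specimen-set specification
#'
#' Describes a set of synthetic cylindrical specimens emulating the
#' seven-sample test series: nominal 18 mm x 12 mm cylinders with small
#' geometric spread and log-normal inter-specimen spread on every shear
#' modulus.
#'
#' @param n_specimens Number of specimens (default 7).
#' @param base_material Ground-truth centre [prony_material()]; default
#'   G_inf = 200 Pa, G_i = (500, 300, 200) Pa, soft-tissue-scale moduli.
#' @param geometry_jitter_sd Fractional s.d. on height and diameter
#'   (default 0.03).
#' @param material_jitter_sd Fractional (log-normal) s.d. on each modulus
#'   (default 0.2).
#' @param seed Integer seed.
#' @return A list of class `specimen_set_spec`.
#' @export
specimen_set_spec <- function(n_specimens = 7L,
                              base_material = prony_material(200, c(500, 300, 200)),
                              geometry_jitter_sd = 0.03,
                              material_jitter_sd = 0.2,
                              seed = 1L) {
  stopifnot(n_specimens >= 1L, inherits(base_material, "prony_material"),
            geometry_jitter_sd >= 0, material_jitter_sd >= 0)
  structure(list(n_specimens = as.integer(n_specimens),
                 base_material = base_material,
                 geometry_jitter_sd = geometry_jitter_sd,
                 material_jitter_sd = material_jitter_sd,
                 seed = as.integer(seed)),
            class = "specimen_set_spec")
}

#' Generate a synthetic study set
#'
#' Draws `n_specimens` independent specimens (jittered geometry and
#' ground-truth material), builds their loadings and force traces, and
#' returns everything needed for identification plus the ground truth for
#' recovery scoring.
#'
#' @param spec A [specimen_set_spec()].
#' @param noise A [noise_model()].
#' @param engine `"analytical"` or `"fe"`.
#' @param loading Optional shared [loading_history()]; default
#'   [make_loading()].
#' @param solver [solver_config()] for the fe engine.
#' @param refinement Mesh refinement passed to [build_mesh()] (fe engine).
#' @return A list of class `specimen_set`: one element per specimen, each a
#'   list with `geometry`, `loading`, `trace`, `ground_truth`, `mesh`
#'   (fe engine only).
#' @export
generate_study_set <- function(spec = specimen_set_spec(),
                               noise = noise_model(),
                               engine = c("analytical", "fe"),
                               loading = make_loading(),
                               solver = solver_config(),
                               refinement = NULL) {
  engine <- match.arg(engine)
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(spec$seed)
  base <- spec$base_material
  draws <- lapply(seq_len(spec$n_specimens), function(i) {
    gj <- stats::rnorm(2, 0, spec$geometry_jitter_sd)
    sdlog <- sqrt(log(1 + spec$material_jitter_sd^2))
    mj <- stats::rlnorm(4, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    list(
      geometry = specimen_geometry(
        "cylinder",
        height = 0.012 * exp(gj[1]),
        diameter = 0.018 * exp(gj[2])
      ),
      material = prony_material(
        g_inf = base$g_inf * mj[1],
        g_terms = base$g_terms * mj[2:4],
        beta = base$beta,
        bulk_modulus = base$bulk_modulus
      ),
      noise_seed = spec$seed * 1000L + i
    )
  })
  if (!is.null(old)) assign(".Random.seed", old, globalenv())

  out <- lapply(draws, function(d) {
    mesh <- if (engine == "fe") build_mesh(d$geometry, refinement = refinement) else NULL
    trace <- generate_specimen_trace(
      d$material, d$geometry, loading, noise = noise, engine = engine,
      seed = d$noise_seed, mesh = mesh, solver = solver
    )
    list(geometry = d$geometry, loading = loading, trace = trace,
         ground_truth = d$material, mesh = mesh)
  })
  structure(out, class = "specimen_set", engine = engine, spec = spec)
}

#' Write a specimen set to per-specimen CSV pairs plus a JSON sidecar
#'
#' Writes `specimen<k>_displacement.csv` (`time_s,displacement_m`),
#' `specimen<k>_force.csv` (`time_s,force_n`) and `ground_truth.json`
#' (geometries and true moduli). The sidecar is for scoring only; fitting
#' functions take the CSV traces.
#'
#' @param set A [generate_study_set()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_study_set <- function(set, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  truth <- list()
  for (k in seq_along(set)) {
    sp <- set[[k]]
    disp <- tibble::tibble(
      time_s = sp$loading$time_s,
      displacement_m = sp$loading$strain * sp$geometry$height
    )
    readr::write_csv(disp, file.path(dir, sprintf("specimen%d_displacement.csv", k)))
    write_trace(sp$trace, file.path(dir, sprintf("specimen%d_force.csv", k)))
    truth[[sprintf("specimen%d", k)]] <- list(
      g_inf = sp$ground_truth$g_inf,
      g_terms = sp$ground_truth$g_terms,
      beta = sp$ground_truth$beta,
      bulk_modulus = sp$ground_truth$bulk_modulus,
      height_m = sp$geometry$height,
      diameter_m = sp$geometry$diameter
    )
  }
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
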