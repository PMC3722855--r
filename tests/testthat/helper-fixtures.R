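# Shared fixtures, built in code. Expensive FE artefacts are memoised so
# test files can share one solve.

ref_material <- function() prony_material(200, c(500, 300, 200))

ref_loading <- function(sample_rate = 1000) {
  make_loading(ramp_time = 0.1, hold_strain = 0.5, total_time = 4,
               sample_rate = sample_rate)
}

# unit cube, single element: homogeneous simple shear, fully prescribed
unit_cube_mesh <- function() {
  build_mesh(specimen_geometry("cube", height = 1, side = 1),
             refinement = c(1, 1, 1))
}

# short solver schedule for coarse-mesh tests
fast_solver <- function() solver_config(n_ramp_steps = 30, n_hold_steps = 60)

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# coarse-cylinder FE solution shared across solver/census/study tests
coarse_cylinder_solution <- function() {
  cached("coarse_sol", {
    mesh <- build_mesh(specimen_geometry(), refinement = "coarse")
    solve_shear(mesh, ref_material(), ref_loading(), config = fast_solver())
  })
}
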