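test_that("elastic single-element cube reproduces homogeneous simple shear", {
  mesh <- unit_cube_mesh()
  el <- prony_material(1000, c(0, 0, 0))
  ld <- make_loading(ramp_time = 0.1, hold_strain = 1e-4, total_time = 1,
                     sample_rate = 100)
  sol <- solve_shear(mesh, el, ld, config = solver_config(10, 20))
  area <- mesh$geometry$area
  f_expect <- 1000 * 1e-4 * area
  expect_equal(tail(sol$force_trace$force_n, 1), f_expect,
               tolerance = 1e-3)
})

test_that("small-strain elastic shear of a multi-element cube matches
           G * gamma * A within 0.5%", {
  geo <- specimen_geometry("cube", height = 0.012)
  mesh <- build_mesh(geo, refinement = c(3, 3, 3))
  el <- prony_material(800, c(0, 0, 0))
  gam <- 1e-4
  ld <- make_loading(ramp_time = 0.1, hold_strain = gam, total_time = 0.5,
                     sample_rate = 100)
  sol <- solve_shear(mesh, el, ld, config = solver_config(10, 10))
  expect_equal(max(sol$force_trace$force_n), 800 * gam * geo$area,
               tolerance = 5e-3)
})

test_that("viscoelastic single-element FE agrees with the 1-D recursion
           within 2% at all times", {
  mesh <- unit_cube_mesh()
  m <- ref_material()
  ld <- ref_loading()
  sol <- solve_shear(mesh, m, ld)
  gam <- approx(ld$time_s, ld$strain, xout = sol$times, rule = 2)$y
  ld_solver <- tibble::tibble(time_s = sol$times, strain = gam)
  ref <- stress_recursive(m, ld_solver)
  area <- mesh$geometry$area
  rel <- abs(sol$force_trace$force_n / area - ref$stress_pa)[-1] /
    max(ref$stress_pa)
  expect_lt(max(rel), 0.02)
  # peak values in particular
  expect_equal(max(sol$force_trace$force_n) / area, max(ref$stress_pa),
               tolerance = 0.02)
})

test_that("near-incompressibility holds: volume change below 0.1% at peak", {
  sol <- coarse_cylinder_solution()
  v <- pi * 0.009^2 * 0.012
  expect_lt(abs(sol$volume_change_peak) / v, 1e-3)
})

test_that("cylinder strain field is heterogeneous with most elements below
           the nominal strain", {
  sol <- coarse_cylinder_solution()
  s <- abs(sol$element_strains_at_peak)
  expect_gt(mean(s < 0.5), 0.5)
  # and clearly non-uniform
  expect_gt(diff(range(s)), 0.1)
})

test_that("strain census partitions the element set", {
  sol <- coarse_cylinder_solution()
  cen <- strain_census(sol, bin_edges = c(0, 0.3, 0.45, 0.5, Inf))
  expect_identical(sum(cen$count), sol$mesh$n_elements)
  expect_equal(sum(cen$fraction), 1)
  expect_error(strain_census(sol, bin_edges = 0.5), "two bin edges")

  # homogeneous single-element cube: everything in the bin containing 0.5
  cube <- solve_shear(unit_cube_mesh(), ref_material(), ref_loading(),
                      config = solver_config(10, 20))
  cen1 <- strain_census(cube, bin_edges = c(0, 0.45, 0.5, 0.55, 1))
  expect_equal(cen1$fraction[cen1$lower == 0.5], 1)
})

test_that("solver reuses a prebuilt operator and rejects bad configs", {
  mesh <- unit_cube_mesh()
  op <- build_fe_operator(mesh)
  m <- ref_material()
  ld <- make_loading(total_time = 1, sample_rate = 100)
  a <- solve_shear(mesh, m, ld, config = solver_config(5, 10))
  b <- solve_shear(mesh, m, ld, config = solver_config(5, 10), operator = op)
  expect_equal(a$force_trace$force_n, b$force_trace$force_n)
  expect_error(solver_config(0, 10))
})
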