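# Study-pipeline tests run on deliberately small meshes and short solver
# schedules; the full-scale numbers live in the acceptance suite.

test_that("convergence table is zero at the finest level and shrinks with
           refinement on a proportional family", {
  tab <- run_convergence(
    specimen_geometry(), ref_material(), ref_loading(),
    levels = list(c(3, 1, 1, 3), c(5, 2, 2, 5), c(7, 3, 3, 7)),
    solver = solver_config(10, 20)
  )
  expect_equal(tab$max_deviation_pct[3], 0)
  expect_true(all(diff(tab$max_deviation_pct) < 0))
  expect_error(run_convergence(specimen_geometry(), ref_material(),
                               ref_loading(), levels = list(c(3, 1, 1, 3))),
               "3 refinement levels")
})

test_that("mode comparison reproduces the qualitative fit-mode ordering on a
           small synthetic specimen", {
  spec <- specimen_set_spec(n_specimens = 1, geometry_jitter_sd = 0,
                            material_jitter_sd = 0, seed = 2)
  set <- generate_study_set(spec, engine = "fe", loading = ref_loading(),
                            solver = fast_solver(), refinement = "coarse")
  res <- run_mode_comparison(set, solver = fast_solver(),
                             modes = c("analytical_no_ramp",
                                       "analytical_with_ramp"))
  cmp <- res$comparison
  expect_identical(nrow(cmp), 2L)
  wr <- cmp[cmp$mode == "analytical_with_ramp", ]
  nr <- cmp[cmp$mode == "analytical_no_ramp", ]
  # both analytical modes under-predict the 3-D peak; no-ramp is softest
  expect_lt(wr$peak_force_error, 0)
  expect_lt(nr$peak_force_error, wr$peak_force_error)
  expect_lt(nr$g0, wr$g0)
  expect_s3_class(res$moduli_summary, "tbl_df")
})

test_that("height reduction raises the normalised peak force and the
           area-matched cube stays within a few percent of the cylinder", {
  m <- ref_material()
  ld <- ref_loading()
  geo <- specimen_geometry()
  data <- generate_specimen_trace(m, geo, ld, engine = "fe",
                                  mesh = build_mesh(geo, refinement = "coarse"),
                                  solver = fast_solver())
  tab <- run_sensitivity(m, geo, ld, data_peak = max(data$force_n),
                         height_factors = c(1, 0.7),
                         solver = fast_solver(),
                         cylinder_refinement = "coarse",
                         cube_refinement = c(6, 6, 4))
  cyl <- tab[tab$shape == "cylinder", ]
  expect_gt(cyl$peak_ratio[cyl$height_factor == 0.7],
            cyl$peak_ratio[cyl$height_factor == 1])
  cube1 <- tab$peak_force_n[tab$shape == "cube" & tab$height_factor == 1]
  cyl1 <- tab$peak_force_n[tab$shape == "cylinder" & tab$height_factor == 1]
  expect_equal(cube1 / cyl1, 1, tolerance = 0.05)
})

test_that("reports serialise losslessly and an empty study writes headers
           without crashing", {
  dir <- withr::local_tempdir()
  empty <- study_report(config = list(tag = "empty"))
  paths <- report(empty, dir, plots = FALSE)
  expect_true(all(file.exists(paths)))
  back <- read_study_report(dir)
  expect_null(back$mode_comparison)
  expect_identical(back$config_hash, empty$config_hash)

  filled <- study_report(
    census = strain_census(coarse_cylinder_solution()),
    convergence = tibble::tibble(level = c("a", "b", "c"),
                                 n_elements = c(10L, 20L, 40L),
                                 max_deviation_pct = c(1, 0.5, 0)),
    config = list(tag = "filled")
  )
  report(filled, dir, plots = TRUE)
  expect_gt(file.size(file.path(dir, "strain_census.pdf")), 0)
  back2 <- read_study_report(dir)
  expect_equal(back2$census$fraction, filled$census$fraction)
  expect_equal(back2$convergence$max_deviation_pct,
               filled$convergence$max_deviation_pct)

  # byte-identical JSON under re-write (end-to-end determinism)
  dir2 <- withr::local_tempdir()
  report(filled, dir2, plots = FALSE)
  expect_identical(readLines(file.path(dir, "study_report.json")),
                   readLines(file.path(dir2, "study_report.json")))
})

test_that("averaged reduced-relaxation curves carry one value per mode and
           time", {
  m <- ref_material()
  ld <- ref_loading()
  fit <- fit_analytical(stress_recursive(m, ld), ld, mode = "with_ramp")
  fits <- list(list(analytical_with_ramp = fit),
               list(analytical_with_ramp = fit))
  cur <- relaxation_curves(fits, times = c(0.01, 0.1, 1))
  expect_identical(nrow(cur), 3L)
  expect_equal(cur$g_reduced,
               reduced_relaxation(fit$material, c(0.01, 0.1, 1)))
})
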