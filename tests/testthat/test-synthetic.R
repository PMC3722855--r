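test_that("make_loading builds the canonical ramp-and-hold signal", {
  ld <- make_loading()
  expect_equal(approx(ld$time_s, ld$strain, 0.05)$y, 0.25)
  expect_true(all(ld$strain[ld$time_s >= 0.1] == 0.5))
  # integral of the strain rate over the ramp equals the hold strain
  ramp <- ld$time_s <= 0.1
  rate <- diff(ld$strain[ramp]) / diff(ld$time_s[ramp])
  expect_equal(sum(rate * diff(ld$time_s[ramp])), 0.5, tolerance = 1e-9)
  expect_error(make_loading(ramp_time = 5, total_time = 4), "less than")
})

test_that("noise-free analytical traces equal recursion times area and are
           deterministic", {
  m <- ref_material()
  geo <- specimen_geometry()
  ld <- ref_loading(200)
  tr <- generate_specimen_trace(m, geo, ld, engine = "analytical", seed = 7)
  ref <- stress_recursive(m, ld)
  expect_equal(tr$force_n, ref$stress_pa * geo$area)
  expect_identical(attr(tr, "ground_truth")$g0, m$g0)

  nm <- noise_model(hold_noise_sd = 0.002, burst_amplitude = 0.01)
  a <- generate_specimen_trace(m, geo, ld, noise = nm, seed = 11)
  b <- generate_specimen_trace(m, geo, ld, noise = nm, seed = 11)
  c <- generate_specimen_trace(m, geo, ld, noise = nm, seed = 12)
  expect_identical(a$force_n, b$force_n)
  expect_false(identical(a$force_n, c$force_n))
})

test_that("burst noise is near zero-mean so light noise barely moves the
           fitted moduli", {
  m <- ref_material()
  geo <- specimen_geometry()
  ld <- ref_loading()
  nm <- noise_model(hold_noise_sd = 0, burst_amplitude = 5e-4)
  noisy <- generate_specimen_trace(m, geo, ld, noise = nm, seed = 3)
  clean <- generate_specimen_trace(m, geo, ld, seed = 3)
  d <- noisy$force_n - clean$force_n
  # integral of each burst ~ 0 relative to its rectified magnitude
  expect_lt(abs(mean(d)), 0.05 * mean(abs(d)) + 1e-12)

  fit_c <- fit_analytical(force_to_stress(clean, geo), ld, mode = "with_ramp")
  fit_n <- fit_analytical(force_to_stress(noisy, geo), ld, mode = "with_ramp")
  err_c <- max(abs(c(fit_c$material$g_inf, fit_c$material$g_terms) -
                     c(200, 500, 300, 200)) / c(200, 500, 300, 200))
  err_n <- max(abs(c(fit_n$material$g_inf, fit_n$material$g_terms) -
                     c(200, 500, 300, 200)) / c(200, 500, 300, 200))
  expect_lt(err_n, max(2 * err_c, 0.02))
})

test_that("study sets honour size, jitter and seeding", {
  ld <- ref_loading(200)
  spec <- specimen_set_spec(n_specimens = 7, seed = 5)
  set <- generate_study_set(spec, engine = "analytical", loading = ld)
  expect_length(set, 7)
  g0s <- vapply(set, function(s) s$ground_truth$g0, numeric(1))
  expect_identical(length(unique(g0s)), 7L)

  # zero jitter: all specimens identical
  spec0 <- specimen_set_spec(n_specimens = 3, geometry_jitter_sd = 0,
                             material_jitter_sd = 0, seed = 5)
  set0 <- generate_study_set(spec0, engine = "analytical", loading = ld)
  expect_equal(set0[[1]]$ground_truth, set0[[3]]$ground_truth)
  expect_equal(set0[[1]]$trace$force_n, set0[[2]]$trace$force_n)

  # same seed reproduces, different seed varies
  set_a <- generate_study_set(spec, engine = "analytical", loading = ld)
  expect_equal(set[[2]]$trace$force_n, set_a[[2]]$trace$force_n)
  spec_b <- specimen_set_spec(n_specimens = 7, seed = 6)
  set_b <- generate_study_set(spec_b, engine = "analytical", loading = ld)
  expect_false(identical(
    vapply(set_b, function(s) s$ground_truth$g0, numeric(1)), g0s))
})

test_that("study sets serialise to CSV pairs plus a ground-truth sidecar", {
  dir <- withr::local_tempdir()
  ld <- ref_loading(100)
  spec <- specimen_set_spec(n_specimens = 2, seed = 9)
  set <- generate_study_set(spec, engine = "analytical", loading = ld)
  write_study_set(set, dir)
  expect_true(file.exists(file.path(dir, "specimen1_force.csv")))
  expect_true(file.exists(file.path(dir, "specimen2_displacement.csv")))
  truth <- jsonlite::read_json(file.path(dir, "ground_truth.json"))
  expect_length(truth, 2)
  expect_equal(truth$specimen1$g_inf, set[[1]]$ground_truth$g_inf)
  # traces re-read from disk match what was generated
  back <- read_trace(file.path(dir, "specimen1_force.csv"))
  expect_equal(back$force_n, set[[1]]$trace$force_n)
})
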