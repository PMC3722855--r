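test_that("force/stress and displacement/strain conversions use area and
           height", {
  geo <- specimen_geometry()  # 18 mm circle
  ft <- viscofit:::new_force_trace(c(0, 1, 2), c(0, 1, 2))
  st <- force_to_stress(ft, geo)
  expect_equal(st$stress_pa[2], 1 / (pi * 0.009^2), tolerance = 1e-12)
  expect_equal(st$stress_pa[1], 0)

  disp <- tibble::tibble(time_s = c(0, 0.1, 0.2),
                         displacement_m = c(0, 6e-3, 6e-3))
  ld <- displacement_to_strain(disp, geo)
  expect_equal(max(ld$strain), 0.5)
  expect_equal(attr(ld, "ramp_time"), 0.1)
})

test_that("SSE objective behaves like a discrete L2 distance on the log
           grid", {
  spec <- objective_spec(n_points = 50, t_min = 1e-2)
  tr <- step_response(ref_material(), 0.5, c(0.001, 10^seq(-2, log10(4),
                                                           length.out = 300)))
  expect_equal(sse_objective(tr, tr, spec), 0)

  shifted <- tr
  shifted$stress_pa <- shifted$stress_pa + 3
  expect_equal(sse_objective(shifted, tr, spec), 50 * 9, tolerance = 1e-9)

  # two-point hand oracle: constant traces 5 and 2 -> n * (5-2)^2
  a <- viscofit:::new_stress_trace(c(0.001, 4), c(5, 5))
  b <- viscofit:::new_stress_trace(c(0.001, 4), c(2, 2))
  spec10 <- objective_spec(n_points = 10, t_min = 0.01)
  expect_equal(sse_objective(a, b, spec10), 10 * 9)

  expect_error(sse_objective(a, viscofit:::new_force_trace(c(0.001, 4), c(1, 1)),
                             spec10), "same kind")
})

test_that("SSE is insensitive to the traces' sampling rate once interpolated
           onto the comparison grid", {
  m <- ref_material()
  spec <- objective_spec()
  mk <- function(rate) {
    ld <- ref_loading(sample_rate = rate)
    stress_recursive(m, ld)
  }
  data <- mk(1000)
  pert <- prony_material(210, c(520, 310, 190))
  model_hi <- stress_recursive(pert, ref_loading(400))
  model_lo <- stress_recursive(pert, ref_loading(100))
  s_hi <- sse_objective(model_hi, data, spec)
  s_lo <- sse_objective(model_lo, data, spec)
  expect_equal(s_lo / s_hi, 1, tolerance = 0.01)
})

test_that("with-ramp fit recovers its own generating parameters within 1%", {
  m <- ref_material()
  ld <- ref_loading()
  data <- stress_recursive(m, ld)
  fit <- fit_analytical(data, ld, mode = "with_ramp")
  truth <- c(200, 500, 300, 200)
  est <- c(fit$material$g_inf, fit$material$g_terms)
  expect_true(all(abs(est - truth) / truth < 0.01))
  expect_equal(fit$mode, "analytical_with_ramp")
  expect_true(all(est >= 0))
})

test_that("no-ramp fit recovers perfect-step data within 1% but
           under-estimates G0 on ramped data", {
  m <- ref_material()
  ld <- ref_loading()
  # perfect-step data expressed on the test clock (step at ramp end)
  t_all <- ld$time_s
  step_data <- step_response(m, 0.5, pmax(t_all - 0.1, 0))
  step_data$time_s <- t_all
  fit_step <- fit_analytical(step_data, ld, mode = "no_ramp")
  est <- c(fit_step$material$g_inf, fit_step$material$g_terms)
  expect_true(all(abs(est - c(200, 500, 300, 200)) / c(200, 500, 300, 200)
                  < 0.01))

  # ramped data fitted as if it were a step: instantaneous modulus drops
  ramp_data <- stress_recursive(m, ld)
  fit_nr <- fit_analytical(ramp_data, ld, mode = "no_ramp")
  expect_lt(fit_nr$material$g0, m$g0)
})

test_that("fit results expose broom-style tidy and glance methods", {
  m <- ref_material()
  ld <- ref_loading()
  fit <- fit_analytical(stress_recursive(m, ld), ld, mode = "with_ramp")
  td <- tidy(fit)
  expect_identical(td$term, c("g_inf", "g1", "g2", "g3"))
  expect_identical(td$beta, c(NA, 1, 10, 100))
  gl <- glance(fit)
  expect_identical(nrow(gl), 1L)
  expect_gte(gl$sse, 0)
  expect_identical(gl$g0, fit$material$g0)
})
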