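test_that("prony_material enforces its invariants", {
  m <- ref_material()
  expect_equal(m$g0, 1200)
  expect_error(prony_material(-1, c(0, 0, 0)), "non-negative")
  expect_error(prony_material(100, c(1, -2, 3)), "non-negative")
  expect_error(prony_material(100, c(1, 2, 3), beta = c(10, 1, 100)),
               "increasing")
  expect_error(prony_material(100, c(1, 2, 3), beta = c(0, 1, 2)),
               "positive")
})

test_that("relaxation modulus matches the exponential-sum evaluation", {
  # elastic limit and instantaneous value
  el <- prony_material(1000, c(0, 0, 0))
  expect_equal(relaxation_modulus(el, c(0, 0.5, 10)), rep(1000, 3))
  m <- ref_material()
  expect_equal(relaxation_modulus(m, 0), m$g0)
  # direct evaluation of the sum at t = 0.01 s as oracle
  t <- 0.01
  oracle <- 200 + 500 * exp(-1 * t) + 300 * exp(-10 * t) + 200 * exp(-100 * t)
  expect_equal(relaxation_modulus(m, t), oracle, tolerance = 1e-14)
  expect_error(relaxation_modulus(m, -1), "non-negative")
})

test_that("relaxation modulus is non-increasing and tends to g_inf", {
  grid <- seq(0, 10, length.out = 400)
  for (seed in 1:5) {
    set.seed(seed)
    m <- prony_material(runif(1, 0, 500), runif(3, 0, 800))
    g <- relaxation_modulus(m, grid)
    expect_true(all(diff(g) <= 1e-12))
    expect_equal(relaxation_modulus(m, 1e4), m$g_inf, tolerance = 1e-10)
  }
})

test_that("step response scales the relaxation modulus by the held strain", {
  m <- ref_material()
  times <- c(0, 0.01, 0.1, 1)
  expect_equal(step_response(m, 0, times)$stress_pa, rep(0, 4))
  el <- prony_material(1000, c(0, 0, 0))
  expect_equal(step_response(el, 0.5, times)$stress_pa, rep(500, 4))
  oracle <- 200 + 500 * exp(-0.01) + 300 * exp(-0.1) + 200 * exp(-1)
  expect_equal(step_response(m, 0.5, 0.01)$stress_pa, 0.5 * oracle)
  expect_error(step_response(m, 1.5, times), "0, 1")
})

test_that("reduced relaxation follows the long-term-modulus normalisation", {
  el <- prony_material(1000, c(0, 0, 0))
  expect_equal(reduced_relaxation(el, c(0, 1, 5)), rep(1, 3))
  m <- ref_material()
  expect_equal(reduced_relaxation(m, 0), m$g0 / m$g_inf)
  oracle <- (200 + 500 * exp(-0.1) + 300 * exp(-1) + 200 * exp(-10)) / 200
  expect_equal(reduced_relaxation(m, 0.1), oracle, tolerance = 1e-14)
  expect_error(reduced_relaxation(prony_material(0, c(1, 1, 1)), 1), "g_inf")
})

test_that("recursive stress is elastic without Prony terms and matches the
           step response after a fast jump", {
  el <- prony_material(750, c(0, 0, 0))
  ld <- ref_loading(sample_rate = 200)
  out <- stress_recursive(el, ld)
  expect_equal(out$stress_pa, 750 * ld$strain)

  # single fast jump then hold: converges to the perfect-step response
  m <- ref_material()
  for (jump in c(1e-3, 1e-4)) {
    time <- c(0, jump, jump + 10^seq(-3, log10(4), length.out = 120))
    strain <- c(0, rep(0.5, length(time) - 1L))
    ld_j <- loading_history(time, strain, ramp_time = jump, hold_strain = 0.5)
    got <- stress_recursive(m, ld_j)$stress_pa[-(1:2)]
    want <- step_response(m, 0.5, time[-(1:2)])$stress_pa
    err <- max(abs(got - want) / want)
    expect_lt(err, 20 * jump)  # first-order in the jump duration
  }
})

test_that("recursive stress equals trapezoidal quadrature of the hereditary
           integral on a fine grid", {
  m <- ref_material()
  # 0.1 s ramp to 0.5 then hold; quadrature grid well under ramp_time/1000
  dt <- 5e-5
  time <- seq(0, 1, by = dt)
  strain <- pmin(time / 0.1, 1) * 0.5
  ld <- loading_history(time, strain, ramp_time = 0.1, hold_strain = 0.5)
  rec <- stress_recursive(m, ld)
  at <- unique(round(seq(101, length(time), length.out = 25)))
  quad <- stress_quadrature(m, ld, at = at)
  rel <- abs(rec$stress_pa[at] - quad$stress_pa) / abs(quad$stress_pa)
  expect_lt(max(rel), 1e-6)
})

test_that("recursive update converges first order in the step for smooth
           strain and is non-increasing during a perfect hold", {
  m <- ref_material()
  smooth_loading <- function(n) {
    t <- seq(0, 0.2, length.out = n + 1L)
    s <- 0.25 * (1 - cos(pi * t / 0.2))
    loading_history(t, s, ramp_time = 0.2, hold_strain = 0.5)
  }
  ref <- stress_recursive(m, smooth_loading(3200))
  err <- vapply(c(100, 200, 400), function(n) {
    got <- stress_recursive(m, smooth_loading(n))
    idx <- match(round(got$time_s, 12), round(ref$time_s, 12))
    max(abs(got$stress_pa - ref$stress_pa[idx]), na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(err) < 0))
  # halving the step roughly halves the error (first order)
  expect_gt(err[1] / err[2], 1.6)
  expect_gt(err[2] / err[3], 1.6)

  hold <- stress_recursive(m, ref_loading(500))
  post <- hold$time_s >= 0.1
  expect_true(all(diff(hold$stress_pa[post]) <= 1e-12))
})
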