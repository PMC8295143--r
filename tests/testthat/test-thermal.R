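uniform_field <- function(grid, value) {
  structure(list(E = matrix(value, grid$nx, grid$ny), applied_voltage = NA),
            class = "field_magnitude")
}
uniform_source <- function(grid, q) {
  structure(list(Q = matrix(q, grid$nx, grid$ny), duty = NA), class = "source_term")
}

test_that("the Joule source is duty-scaled sigma |E|^2", {
  g <- coarse_grid(spacing = 1)
  props <- tissue_properties()
  prot <- pulse_protocol(90, 100, 1)
  src <- joule_source(uniform_field(g, 1e5), props, prot, g)
  tis <- g$region == 0L
  expect_equal(unique(src$Q[tis]), 1e-4 * 0.1483 * 1e10)
  expect_true(all(src$Q[!tis] == 0))
  # zero field, zero source
  src0 <- joule_source(uniform_field(g, 0), props, prot, g)
  expect_true(all(src0$Q == 0))
  # linear in the duty cycle: halving the pulse width halves the source
  src_half <- joule_source(uniform_field(g, 1e5), props, pulse_protocol(90, 50, 1), g)
  expect_equal(src_half$Q[tis], src$Q[tis] / 2)
  expect_error(pulse_protocol(10, 2e6, 1), "duty")
})

test_that("uniform 37 C with no source is a stationary state", {
  g <- coarse_grid(spacing = 1)
  props <- tissue_properties(); blood <- blood_constants()
  T <- matrix(NA_real_, g$nx, g$ny); T[g$region == 0L] <- 37
  for (i in 1:3) T <- step_bioheat(T, uniform_source(g, 0), g, props, blood, dt = 1)
  expect_equal(T[g$region == 0L], rep(37, sum(g$region == 0L)), tolerance = 1e-12)
})

test_that("perfusion relaxation matches the backward-Euler closed form exactly", {
  g <- coarse_grid(spacing = 1)
  props <- tissue_properties(); blood <- blood_constants()
  rho_c <- 1050 * 3400
  P <- 1000 * 3640 * 5e-4
  T0 <- 47; dt <- 0.5; n <- 8
  T <- matrix(NA_real_, g$nx, g$ny); T[g$region == 0L] <- T0
  st <- ireplan:::.thermal_stepper(g, props, blood, dt)
  for (i in seq_len(n)) T <- st(T, matrix(0, g$nx, g$ny))
  expected <- 37 + (T0 - 37) * (1 + dt * P / rho_c)^(-n)
  expect_equal(max(abs(T[g$region == 0L] - expected)), 0, tolerance = 1e-9)
  # continuous-time limit for reference: same constant to first order
  expect_equal(expected, 37 + (T0 - 37) * exp(-P * n * dt / rho_c), tolerance = 1e-3)
})

test_that("pure heating with perfusion off obeys the exact energy balance", {
  g <- coarse_grid(spacing = 1)
  props <- tissue_properties(); blood <- blood_constants()
  q <- 2e5; dt <- 0.5; n <- 6
  T <- matrix(NA_real_, g$nx, g$ny); T[g$region == 0L] <- 37
  st <- ireplan:::.thermal_stepper(g, props, blood, dt, perfusion = FALSE)
  for (i in seq_len(n)) T <- st(T, matrix(q, g$nx, g$ny))
  # uniform source, insulated boundaries: Delta T = Q t / (rho c_p), exact
  expect_equal(unique(round(T[g$region == 0L], 9)),
               round(37 + q * n * dt / (1050 * 3400), 9))
})

test_that("a non-uniform treatment conserves energy with perfusion off", {
  cfg <- coarse_config(spacing = 1, dt = 0.5, perfusion = FALSE)
  sim <- simulate_protocol(10, 10, 3000, 10, 100, cfg)
  g <- sim$grid
  tis <- g$region == 0L
  lhs <- 1050 * 3400 * sum(sim$T_final[tis] - 37) * g$h^2
  rhs <- sim$protocol$duration * sum(sim$source$Q[tis]) * g$h^2
  expect_lt(abs(lhs - rhs) / rhs, 0.005)
})

test_that("temperature stays above the initial 37 C under non-negative heating", {
  sim <- coarse_optimal_sim()
  tis <- sim$grid$region == 0L
  expect_gte(min(sim$T_final[tis]), 37)
  expect_gte(min(sim$series$T_center_C), 37)
})

test_that("zero-duration treatment leaves the tissue at 37 C", {
  cfg <- coarse_config(spacing = 1)
  sim <- simulate_protocol(10, 10, 3000, 0, 100, cfg)
  expect_equal(sim$max_temperature, 37)
  expect_equal(nrow(sim$series), 0L)
})

test_that("maximum temperature is monotone in the pulse number", {
  cfg <- coarse_config(spacing = 1, dt = 1)
  tmax <- vapply(c(30, 60, 90), function(n)
    simulate_protocol(10, 10, 3000, n, 100, cfg)$max_temperature, numeric(1))
  expect_true(all(diff(tmax) > 0))
})

test_that("final center temperature is stable under time-step refinement", {
  cfg1 <- coarse_config(spacing = 1, dt = 0.1)
  cfg2 <- coarse_config(spacing = 1, dt = 0.05)
  s1 <- simulate_protocol(10, 10, 3000, 10, 100, cfg1)
  s2 <- simulate_protocol(10, 10, 3000, 10, 100, cfg2)
  c1 <- s1$grid$center_ij
  expect_lt(abs(s1$T_final[c1[1], c1[2]] - s2$T_final[c1[1], c1[2]]), 0.1)
})

test_that("the center-line profile peaks inside the active span", {
  sim <- coarse_optimal_sim()
  g <- sim$grid
  i <- g$center_ij[1]
  prof <- sim$T_final[i, ]
  ok <- !is.na(prof)
  # active span: 10-20 mm depth
  js <- which(ok)
  peak_j <- js[which.max(prof[js])]
  peak_depth <- g$y[peak_j] * 1e3
  expect_gt(peak_depth, 10); expect_lt(peak_depth, 20)
  # decays from the peak toward the surface and past the tip
  surface_T <- prof[js[1]]
  deep_T <- prof[js[length(js)]]
  expect_lt(surface_T, max(prof[js]))
  expect_lt(deep_T, max(prof[js]))
})
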