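# Synthetic cross-sectional grid: two disk electrodes, no shaft. Used to
# compare the solver against the closed-form two-wire potential.
disk_grid <- function(width = 120, spacing = 0.5, d = 16, a = 2, voltage = 1000) {
  g <- build_grid(domain_spec(width, width, spacing, margin = 10),
                  electrode_config(active_length = 10, distance = d, voltage = voltage))
  mm <- 1e-3
  cx <- width / 2 * mm
  xl <- cx - d / 2 * mm
  xr <- cx + d / 2 * mm
  dl <- outer(g$x, g$y, function(x, y) sqrt((x - xl)^2 + (y - cx)^2))
  dr <- outer(g$x, g$y, function(x, y) sqrt((x - xr)^2 + (y - cx)^2))
  reg <- matrix(0L, g$nx, g$ny)
  reg[dl <= a * mm + 1e-12] <- 1L
  reg[dr <= a * mm + 1e-12] <- 2L
  g$region <- reg
  g
}

test_that("zero applied voltage gives identically zero potential and field", {
  g <- coarse_grid(voltage = 0)
  pot <- solve_potential(g, tissue_properties())
  fld <- field_magnitude(pot, g)
  expect_true(all(pot$V[g$region == 0L] == 0))
  expect_true(all(fld$E == 0))
})

test_that("the discrete maximum principle holds and Dirichlet data are exact", {
  g <- coarse_grid(voltage = 3000)
  for (mode in c("constant_sigma", "field_dependent")) {
    pot <- solve_potential(g, tissue_properties(), mode = mode)
    V <- pot$V[!is.na(pot$V)]
    expect_gte(min(V), 0)
    expect_lte(max(V), 3000)
    expect_true(all(pot$V[g$region == 1L] == 3000))
    expect_true(all(pot$V[g$region == 2L] == 0))
  }
})

test_that("the constant-sigma problem is linear in the applied voltage", {
  g1 <- coarse_grid(voltage = 1000)
  g3 <- coarse_grid(voltage = 3000)
  props <- flat_sigma_props()
  p1 <- solve_potential(g1, props, mode = "constant_sigma")
  p3 <- solve_potential(g3, props, mode = "constant_sigma")
  tis <- g1$region == 0L
  expect_equal(p3$V[tis], 3 * p1$V[tis], tolerance = 1e-9)
  e1 <- field_magnitude(p1, g1)
  e3 <- field_magnitude(p3, g3)
  expect_equal(e3$E, 3 * e1$E, tolerance = 1e-9)
})

test_that("Picard iteration reports a converged self-consistent conductivity", {
  g <- coarse_grid(voltage = 3000)
  props <- tissue_properties()
  pot <- solve_potential(g, props, tol = 1e-8)
  expect_lt(pot$residual, 1e-8)
  # conductivity on record equals sigma(|E|) of the converged field up to
  # the under-relaxed fixed-point tolerance
  fld <- field_magnitude(pot, g)
  tis <- g$region == 0L
  expect_lt(max(abs(pot$sigma[tis] - sigma_of_field(props, fld$E[tis]))), 1e-4)
  # the tail of the residual history is decreasing
  h <- pot$residual_history
  if (length(h) > 3) expect_true(all(diff(tail(h, 3)) < 0))
})

test_that("solver matches the two-wire analytic potential on the mid band", {
  g <- disk_grid()
  pot <- solve_potential(g, flat_sigma_props(), mode = "constant_sigma")
  mm <- 1e-3
  c0 <- 60 * mm
  ch <- c(c0 - 8 * mm, c0); cg <- c(c0 + 8 * mm, c0)
  band <- expand.grid(x = g$x[abs(g$x - c0) <= 4.8 * mm],
                      y = g$y[abs(g$y - c0) <= 4.8 * mm])
  ij <- cbind(match(round(band$x, 10), round(g$x, 10)),
              match(round(band$y, 10), round(g$y, 10)))
  Vana <- two_wire_potential(band$x, band$y, ch, cg, 2 * mm, 1000)
  expect_lt(max(abs(pot$V[ij] - Vana)) / 1000, 0.02)
  # midpoint symmetry of the numerical solution
  mid <- c(match(round(c0, 10), round(g$x, 10)), match(round(c0, 10), round(g$y, 10)))
  expect_equal(pot$V[mid[1], mid[2]], 500, tolerance = 0.01)
})

test_that("field post-processing is exact for linear potentials and O(h^2) for the oracle", {
  g <- coarse_grid(voltage = 0, spacing = 1)
  # linear ramp: |E| equals the slope everywhere away from the masked shaft
  a <- 1234
  Vlin <- outer(g$x, rep(1, g$ny)) * a
  E <- ireplan:::.gradient_magnitude(Vlin, g)
  expect_equal(max(abs(E - a)), 0, tolerance = 1e-9)
  # constant potential: zero field
  E0 <- ireplan:::.gradient_magnitude(matrix(5, g$nx, g$ny), g)
  expect_true(all(E0 == 0))
  # finite differences of the analytic two-wire potential converge to the
  # analytic gradient at second order
  err_at <- function(spacing) {
    gg <- disk_grid(spacing = spacing)
    mm <- 1e-3; c0 <- 60 * mm
    ch <- c(c0 - 8 * mm, c0); cg <- c(c0 + 8 * mm, c0)
    Vana <- outer(gg$x, gg$y, function(x, y)
      two_wire_potential(x, y + 1e-7, ch, cg, 2 * mm, 1000))
    En <- ireplan:::.gradient_magnitude(Vana, gg)
    band_i <- which(abs(gg$x - c0) <= 4 * mm)
    band_j <- which(abs(gg$y - c0) <= 4 * mm)
    pts <- expand.grid(i = band_i, j = band_j)
    Ea <- two_wire_field(gg$x[pts$i], gg$y[pts$j] + 1e-7, ch, cg, 2 * mm, 1000)
    max(abs(En[as.matrix(pts)] - Ea) / Ea)
  }
  e1 <- err_at(1); e2 <- err_at(0.5)
  expect_lt(e2, e1 / 3)  # ~ factor 4 expected at second order
})

test_that("center-point field is insensitive to refinement and domain size", {
  props <- tissue_properties()
  center_E <- function(spacing, width = 60) {
    g <- build_grid(domain_spec(width, width, spacing),
                    electrode_config(10, 10, 3000))
    fld <- field_magnitude(solve_potential(g, props), g)
    fld$E[g$center_ij[1], g$center_ij[2]]
  }
  # halving the spacing from the 0.25 mm default
  e_half <- center_E(0.5)
  simf <- fullres_optimal_sim()
  e_default <- simf$field$E[simf$grid$center_ij[1], simf$grid$center_ij[2]]
  expect_lt(abs(e_half - e_default) / e_default, 0.01)
  # doubling the domain at fixed spacing
  e_coarse <- center_E(1)
  e_big <- center_E(1, width = 120)
  expect_lt(abs(e_big - e_coarse) / e_coarse, 0.01)
})
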