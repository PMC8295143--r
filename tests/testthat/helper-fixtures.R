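# Shared fixtures for the test suite. PDE-based fixtures are built lazily
# and cached so independent test files can reuse one solve.

.cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.cache[[key]])) .cache[[key]] <- builder()
  .cache[[key]]
}

# coarse configuration used by most solver tests: 1 mm spacing keeps a
# single solve well under a second
coarse_config <- function(spacing = 1, dt = 0.5, width = 60, height = 60, ...) {
  run_config(domain = domain_spec(width, height, spacing), dt = dt, ...)
}

# the study's optimal protocol at coarse resolution
coarse_optimal_sim <- function() {
  memo("coarse_optimal_sim", function() {
    simulate_protocol(10, 10, 3000, 50, 41.21, coarse_config(spacing = 0.5))
  })
}

# the same protocol at the default (production) resolution; shared between
# the calibration check and the refinement tests
fullres_optimal_sim <- function() {
  memo("fullres_optimal_sim", function() {
    simulate_protocol(10, 10, 3000, 50, 41.21, run_config())
  })
}

# a small constant-sigma potential solve reused by field/area tests
coarse_grid <- function(voltage = 3000, distance = 10, active = 10, spacing = 1) {
  build_grid(domain_spec(60, 60, spacing),
             electrode_config(active_length = active, distance = distance,
                              voltage = voltage))
}

# tissue properties with a flat sigma curve (linear problem)
flat_sigma_props <- function(sigma = 0.1) {
  tissue_properties(sigma_curve = property_curve(c(0, 1e6), c(sigma, sigma),
                                                 "field_magnitude"))
}

table5 <- function() ire_screening_table()

table5_models <- function() {
  memo("table5_models", function() {
    tab <- table5()
    list(area = fit_rsm(tab, tab, "ablation_area_mm2"),
         temperature = fit_rsm(tab, tab, "max_temperature_C"))
  })
}
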