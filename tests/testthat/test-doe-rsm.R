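test_that("the full factorial enumerates all level combinations", {
  expect_equal(nrow(full_factorial()), 162)
  one <- full_factorial(list(factor_spec("a", c(1, 2, 3))))
  expect_equal(one$a, c(1, 2, 3))
  two <- full_factorial(list(factor_spec("a", c(1, 2)), factor_spec("b", c(10, 20, 30))))
  expect_equal(nrow(two), 6)
  expect_equal(two$a, c(1, 1, 1, 2, 2, 2))     # lexicographic order
  expect_equal(two$b, rep(c(10, 20, 30), 2))
  expect_error(full_factorial(list()), "empty")
})

test_that("the L18 array is balanced and matches the screening design", {
  d <- taguchi_L18()
  expect_equal(nrow(d), 18)
  expect_equal(unlist(d[1, -1], use.names = FALSE), c(10, 10, 1000, 30, 40))
  expect_equal(unlist(d[18, -1], use.names = FALSE), c(15, 20, 3000, 60, 40))
  expect_true(all(table(d$active_length_mm) == 9))
  for (f in c("distance_mm", "voltage_V", "pulse_number", "pulse_width_us"))
    expect_true(all(table(d[[f]]) == 6))
  # row-for-row identical to the reference screening table's design columns
  ref <- table5()[, names(d)]
  expect_equal(d, ref)
  expect_error(taguchi_L18(list(factor_spec("a", c(1, 2)))), "L18")
})

test_that("coded/natural mapping round-trips on every level", {
  for (spec in default_factor_specs()) {
    coded <- code_factor(spec$levels, spec)
    expect_equal(decode_factor(coded, spec), spec$levels)
    expect_equal(coded[1], -1)
    expect_equal(coded[length(coded)], 1)
  }
})

test_that("the quadratic fit recovers a noiseless synthetic surface exactly", {
  des <- taguchi_L18()
  truth <- list(intercept = 100,
                linear = c(active_length_mm = 5, distance_mm = -12, voltage_V = 80,
                           pulse_number = 3, pulse_width_us = -7),
                quad = c(distance_mm = 4, voltage_V = -9, pulse_number = 2,
                         pulse_width_us = 6))
  y <- generate_synthetic_responses(des, truth)
  fit <- fit_rsm(des, y, "y")
  cf <- coef(fit$fit)
  expect_equal(unname(cf["(Intercept)"]), 100, tolerance = 1e-8)
  expect_equal(unname(cf["voltage_V"]), 80, tolerance = 1e-8)
  expect_equal(unname(cf["I(distance_mm^2)"]), 4, tolerance = 1e-8)
  expect_equal(unname(cf["I(pulse_width_us^2)"]), 6, tolerance = 1e-8)
  # predictions reproduce the generating surface at off-design points
  newp <- data.frame(active_length_mm = 12, distance_mm = 13, voltage_V = 2400,
                     pulse_number = 45, pulse_width_us = 55)
  Xc <- code_design(newp)
  manual <- 100 + 5 * Xc[[1]] - 12 * Xc[[2]] + 80 * Xc[[3]] + 3 * Xc[[4]] - 7 * Xc[[5]] +
    4 * Xc[[2]]^2 - 9 * Xc[[3]]^2 + 2 * Xc[[4]]^2 + 6 * Xc[[5]]^2
  expect_equal(predict(fit, newp), manual, tolerance = 1e-8)
})

test_that("noisy-replicate coefficient spread matches least-squares theory", {
  des <- taguchi_L18()
  truth <- list(intercept = 50, linear = c(voltage_V = 20, distance_mm = -5),
                quad = c(voltage_V = 3))
  sd_true <- 5
  set.seed(123)
  est <- replicate(200, {
    y <- generate_synthetic_responses(des, truth, noise_sd = sd_true,
                                      seed = sample.int(1e6, 1))
    coef(fit_rsm(des, y, "y")$fit)["voltage_V"]
  })
  expect_equal(mean(est), 20, tolerance = 0.15)
  # theoretical sd of the voltage coefficient: sd * sqrt((X'X)^-1_jj)
  X <- stats::model.matrix(fit_rsm(des, generate_synthetic_responses(des, truth), "y")$fit)
  th_sd <- sd_true * sqrt(solve(crossprod(X))["voltage_V", "voltage_V"])
  expect_lt(abs(sd(est) - th_sd) / th_sd, 0.2)
})

test_that("screening-table ANOVA flags the known significant factors", {
  m <- table5_models()
  at <- rsm_anova(m$temperature)$factors
  expect_true(at$significant[at$factor == "distance_mm"])
  expect_true(at$significant[at$factor == "voltage_V"])
  expect_false(any(at$significant[at$factor %in%
    c("active_length_mm", "pulse_number", "pulse_width_us")]))
  aa <- rsm_anova(m$area)$factors
  expect_lt(aa$p_value[aa$factor == "voltage_V"], 0.001)
  expect_false(any(aa$significant[aa$factor != "voltage_V"]))
})

test_that("ANOVA p-values are null-distributed after permuting the responses", {
  tab <- table5()
  set.seed(99)
  p_al <- replicate(100, {
    sh <- tab
    sh$max_temperature_C <- sample(sh$max_temperature_C)
    f <- rsm_anova(fit_rsm(sh, sh, "max_temperature_C"))$factors
    f$p_value[f$factor == "active_length_mm"]
  })
  expect_gte(mean(p_al > 0.05), 0.9)
})

# independent oracle: dense grid evaluation of the composite desirability
grid_oracle <- function(models, dspec, specs, n = 13) {
  nm <- vapply(specs, function(s) s$name, character(1))
  names(specs) <- nm
  area_range <- models$area$y_range
  dlv <- specs$distance_mm$levels; vlv <- specs$voltage_V$levels
  frange <- c(min(vlv) / (max(dlv) * 1e-3), max(vlv) / (min(dlv) * 1e-3))
  g <- seq(-1, 1, length.out = n)
  best <- -Inf
  for (a in c(-1, 1)) {
    G <- expand.grid(active_length_mm = a, distance_mm = g, voltage_V = g,
                     pulse_number = g, pulse_width_us = g)
    A <- predict(models$area, G, coded = TRUE)
    Tm <- predict(models$temperature, G, coded = TRUE)
    fld <- decode_factor(G$voltage_V, specs$voltage_V) /
      (decode_factor(G$distance_mm, specs$distance_mm) * 1e-3)
    D <- composite_desirability(A, Tm, dspec, area_range, fld, frange)
    best <- max(best, max(D))
  }
  best
}

test_that("the multi-start optimizer attains the brute-force grid maximum", {
  specs <- default_factor_specs()
  des <- taguchi_L18()
  set.seed(11)
  for (case in 1:3) {
    mkcoef <- function(scale) list(
      intercept = runif(1, 100, 200) * scale,
      linear = setNames(runif(5, -1, 1) * 40 * scale,
                        vapply(specs, function(s) s$name, character(1))),
      quad = setNames(runif(4, -1, 1) * 20 * scale,
                      c("distance_mm", "voltage_V", "pulse_number", "pulse_width_us")))
    ya <- generate_synthetic_responses(des, mkcoef(1), seed = case, response = "area")
    # temperature surfaces straddling the 37-50 C desirability window
    yt <- within(generate_synthetic_responses(des, mkcoef(0.1), seed = case + 10,
                                              response = "tmax"),
                 tmax <- tmax / 2 + 40)
    models <- list(area = fit_rsm(des, ya, "area"),
                   temperature = fit_rsm(des, yt, "tmax"))
    dspec <- desirability_spec()
    opt <- optimize_desirability(models, dspec, specs, seed = case)
    slice_best <- max(vapply(opt$slices, function(s) s$desirability, numeric(1)))
    oracle <- grid_oracle(models, dspec, specs)
    expect_gte(slice_best, oracle - 1e-3)
  }
})

test_that("a feasibility island at one corner is found by the optimizer", {
  des <- full_factorial()
  # temperature exceeds the cap everywhere except near the all-low corner
  yt <- generate_synthetic_responses(
    des, list(intercept = 55, linear = c(distance_mm = 2, voltage_V = 2,
                                         pulse_number = 2, pulse_width_us = 2),
              quad = c()), response = "tmax")
  ya <- generate_synthetic_responses(
    des, list(intercept = 100, linear = c(voltage_V = 50), quad = c()),
    response = "area")
  models <- list(area = fit_rsm(des, ya, "area"),
                 temperature = fit_rsm(des, yt, "tmax"))
  opt <- optimize_desirability(models, desirability_spec(include_field = FALSE),
                               default_factor_specs(), seed = 3)
  # only T <= 50 region: sum of coded settings <= -2.5; optimizer must sit
  # inside it
  expect_lte(opt$predicted[["temperature"]], 50 + 1e-6)
  expect_gt(opt$desirability, 0)
})

test_that("a monotone single-response surface is maximized at the box corner", {
  des <- full_factorial()
  ya <- generate_synthetic_responses(
    des, list(intercept = 200, linear = c(voltage_V = 100), quad = c()),
    response = "area")
  yt <- generate_synthetic_responses(
    des, list(intercept = 45, linear = c(), quad = c()), response = "tmax")
  models <- list(area = fit_rsm(des, ya, "area"),
                 temperature = fit_rsm(des, yt, "tmax"))
  opt <- optimize_desirability(models, desirability_spec(include_field = FALSE),
                               seed = 5)
  expect_equal(unname(opt$optimum[["voltage_V"]]), 3000)
})

test_that("main effects tabulate per-level response means", {
  tab <- table5()
  me <- main_effects(tab, tab, "max_temperature_C")
  v <- me[me$factor == "voltage_V", ]
  expect_equal(v$level, c(1000, 2000, 3000))
  expect_equal(v$mean_response[1],
               mean(tab$max_temperature_C[tab$voltage_V == 1000]))
  expect_true(all(diff(v$mean_response) > 0))
})
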