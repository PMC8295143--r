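# End-to-end study orchestration: screening simulations over a design,
# response-surface optimization, and verification re-simulation.

#' Study run configuration
#'
#' Collects every knob of the pipeline with the defaults used throughout:
#' 60 x 60 mm domain, 1 mm electrodes inserted 20 mm, 800 V/cm ablation
#' threshold, 50 C damage limit, 1 Hz pulse delivery.
#'
#' @param domain a [domain_spec()].
#' @param props a [tissue_properties()].
#' @param blood a [blood_constants()].
#' @param diameter electrode diameter, mm.
#' @param insertion_depth mm.
#' @param frequency pulse repetition frequency, Hz.
#' @param dt thermal time step, s.
#' @param ablation_threshold V/m.
#' @param damage_limit degrees C.
#' @param mode electric solver mode.
#' @param perfusion keep the perfusion sink.
#' @param output_dir directory for tables/logs (NULL = none).
#' @param seed RNG seed used by the optimizer's multi-start.
#' @return object of class `run_config`.
#' @export
run_config <- function(domain = domain_spec(), props = tissue_properties(),
                       blood = blood_constants(), diameter = 1.0,
                       insertion_depth = 20, frequency = 1, dt = 0.1,
                       ablation_threshold = 8e4, damage_limit = 50,
                       mode = "field_dependent", perfusion = TRUE,
                       output_dir = NULL, seed = 1) {
  structure(list(domain = domain, props = props, blood = blood,
                 diameter = diameter, insertion_depth = insertion_depth,
                 frequency = frequency, dt = dt,
                 ablation_threshold = ablation_threshold,
                 damage_limit = damage_limit, mode = mode,
                 perfusion = perfusion, output_dir = output_dir, seed = seed),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Every key is optional; omitted keys keep the package defaults. Lengths
#' in mm, pulse width in us, voltage in V (clinician units; converted to SI
#' internally). Recognized blocks: `geometry` (width, height, spacing,
#' margin, diameter, insertion_depth), `properties` (density,
#' heat_capacity, sigma_csv, k_csv, epsr_csv), `blood` (density,
#' heat_capacity, perfusion_rate, temperature, metabolic_heat), `solver`
#' (dt, mode, perfusion, frequency), `thresholds` (ablation_field_V_per_m,
#' damage_temperature_C), `output_dir`, `seed`.
#'
#' @param path YAML file path.
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  g <- y$geometry %||% list()
  p <- y$properties %||% list()
  b <- y$blood %||% list()
  s <- y$solver %||% list()
  th <- y$thresholds %||% list()
  curve_or_null <- function(f, absc) if (is.null(f)) NULL else read_property_curve(f, absc)
  props <- tissue_properties(
    density = p$density %||% 1050,
    heat_capacity = p$heat_capacity %||% 3400,
    k_curve = curve_or_null(p$k_csv, "temperature"),
    sigma_curve = curve_or_null(p$sigma_csv, "field_magnitude"),
    epsr_curve = curve_or_null(p$epsr_csv, "temperature"))
  blood <- blood_constants(
    blood_density = b$density %||% 1000,
    blood_heat_capacity = b$heat_capacity %||% 3640,
    perfusion_rate = b$perfusion_rate %||% 5e-4,
    blood_temperature = b$temperature %||% 37,
    metabolic_heat = b$metabolic_heat %||% 0)
  run_config(
    domain = domain_spec(width = g$width %||% 60, height = g$height %||% 60,
                         spacing = g$spacing %||% 0.25, margin = g$margin %||% 15),
    props = props, blood = blood,
    diameter = g$diameter %||% 1.0,
    insertion_depth = g$insertion_depth %||% 20,
    frequency = s$frequency %||% 1,
    dt = s$dt %||% 0.1,
    ablation_threshold = th$ablation_field_V_per_m %||% 8e4,
    damage_limit = th$damage_temperature_C %||% 50,
    mode = s$mode %||% "field_dependent",
    perfusion = s$perfusion %||% TRUE,
    output_dir = y$output_dir, seed = y$seed %||% 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate one protocol under a run configuration
#'
#' Convenience wrapper building the grid and pulse protocol from the five
#' optimizable parameters and running the coupled solve.
#'
#' @param active_length,distance,voltage,pulse_number,pulse_width the five
#'   IRE parameters (mm, mm, V, count, us).
#' @param config a [run_config()].
#' @return an [ire_simulation][simulate_treatment()].
#' @export
simulate_protocol <- function(active_length, distance, voltage, pulse_number,
                              pulse_width, config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  el <- electrode_config(active_length = active_length, distance = distance,
                         voltage = voltage, diameter = config$diameter,
                         insertion_depth = config$insertion_depth)
  grid <- build_grid(config$domain, el)
  prot <- pulse_protocol(pulse_number, pulse_width, config$frequency)
  simulate_treatment(grid, config$props, config$blood, prot, dt = config$dt,
                     mode = config$mode, perfusion = config$perfusion)
}

#' Run the screening simulations over a design
#'
#' One coupled simulation per design row. Deterministic given the
#' configuration. When `config$output_dir` is set, the response table is
#' written to `responses.csv` there and completed run_ids are skipped on
#' re-runs (resumability); per-run convergence diagnostics go to
#' `screening_log.csv`. A row whose solver fails is recorded with NA
#' responses; the study aborts if more than a quarter of the rows fail.
#'
#' @param design design table from [full_factorial()], [taguchi_L18()] or a
#'   CSV with the same columns.
#' @param config a [run_config()].
#' @return response table (one row per design row).
#' @export
run_screening <- function(design, config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  need <- c("run_id", "active_length_mm", "distance_mm", "voltage_V",
            "pulse_number", "pulse_width_us")
  if (!all(need %in% names(design))) stop("design is missing required columns")
  out_path <- NULL; log_path <- NULL
  done <- NULL
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    out_path <- file.path(config$output_dir, "responses.csv")
    log_path <- file.path(config$output_dir, "screening_log.csv")
    if (file.exists(out_path)) done <- read_response_table(out_path)
  }
  rows <- vector("list", nrow(design))
  logs <- vector("list", nrow(design))
  n_fail <- 0
  for (r in seq_len(nrow(design))) {
    id <- design$run_id[r]
    if (!is.null(done) && id %in% done$run_id) {
      rows[[r]] <- done[done$run_id == id, , drop = FALSE]
      next
    }
    t0 <- proc.time()[["elapsed"]]
    sim <- tryCatch(
      simulate_protocol(design$active_length_mm[r], design$distance_mm[r],
                        design$voltage_V[r], design$pulse_number[r],
                        design$pulse_width_us[r], config),
      error = function(e) e)
    if (inherits(sim, "error")) {
      n_fail <- n_fail + 1
      rows[[r]] <- data.frame(run_id = id,
                              active_length_mm = design$active_length_mm[r],
                              distance_mm = design$distance_mm[r],
                              voltage_V = design$voltage_V[r],
                              pulse_number = design$pulse_number[r],
                              pulse_width_us = design$pulse_width_us[r],
                              ablation_area_mm2 = NA_real_,
                              max_temperature_C = NA_real_,
                              thermal_damage = NA)
      logs[[r]] <- data.frame(run_id = id, status = "error",
                              message = conditionMessage(sim),
                              picard_iterations = NA, residual = NA,
                              wall_s = proc.time()[["elapsed"]] - t0)
      if (n_fail > 0.25 * nrow(design))
        stop("more than 25% of the screening rows failed; aborting the study")
      next
    }
    rows[[r]] <- response_record(sim, threshold = config$ablation_threshold,
                                 damage_limit = config$damage_limit, run_id = id)
    logs[[r]] <- data.frame(run_id = id, status = "ok", message = "",
                            picard_iterations = sim$potential$iterations,
                            residual = sim$potential$residual,
                            wall_s = proc.time()[["elapsed"]] - t0)
  }
  responses <- do.call(rbind, rows)
  if (!is.null(out_path)) {
    write_response_table(responses, out_path)
    lg <- do.call(rbind, logs[!vapply(logs, is.null, logical(1))])
    if (!is.null(lg) && nrow(lg)) utils::write.csv(lg, log_path, row.names = FALSE)
  }
  responses
}

#' Fit, optimize and verify
#'
#' Fits the quadratic response surfaces to a response table, runs the
#' desirability optimization, re-simulates the (rounded-pulse-number)
#' optimal protocol, and reports the optimization-vs-simulation comparison
#' with relative errors in percent, `100 * |RSM - model| / RSM`.
#'
#' @param responses response table (design columns + responses), e.g. from
#'   [run_screening()] or [ire_screening_table()].
#' @param config a [run_config()].
#' @param specs factor specs.
#' @param dspec a [desirability_spec()].
#' @param verify re-simulate at the optimum (set FALSE to skip the PDE).
#' @return object of class `study_report`: `models`, `anova`,
#'   `optimization`, `verification` (response record or NULL),
#'   `comparison` (data.frame response, rsm, models, error_pct),
#'   `thermal_damage`.
#' @export
run_optimization_and_verify <- function(responses, config = run_config(),
                                        specs = default_factor_specs(),
                                        dspec = desirability_spec(),
                                        verify = TRUE) {
  models <- list(
    area = fit_rsm(responses, responses, "ablation_area_mm2", specs),
    temperature = fit_rsm(responses, responses, "max_temperature_C", specs))
  opt <- optimize_desirability(models, dspec, specs, seed = config$seed)
  verification <- NULL; comparison <- NULL; damage <- NA
  if (verify) {
    o <- opt$optimum
    sim <- simulate_protocol(o[["active_length_mm"]], o[["distance_mm"]],
                             o[["voltage_V"]], opt$pulse_number_rounded,
                             o[["pulse_width_us"]], config)
    verification <- response_record(sim, threshold = config$ablation_threshold,
                                    damage_limit = config$damage_limit)
    damage <- verification$thermal_damage
    rel <- function(rsm, mod) 100 * abs(rsm - mod) / abs(rsm)
    comparison <- data.frame(
      response = c("ablation_area_mm2", "max_temperature_C"),
      rsm = c(opt$predicted[["area"]], opt$predicted[["temperature"]]),
      models = c(verification$ablation_area_mm2, verification$max_temperature_C),
      error_pct = c(rel(opt$predicted[["area"]], verification$ablation_area_mm2),
                    rel(opt$predicted[["temperature"]], verification$max_temperature_C)))
  }
  report <- structure(list(models = models,
                           anova = list(area = rsm_anova(models$area),
                                        temperature = rsm_anova(models$temperature)),
                           optimization = opt, verification = verification,
                           comparison = comparison, thermal_damage = damage,
                           responses = responses),
                      class = "study_report")
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    write_study_report(report, file.path(config$output_dir, "study_report.json"))
  }
  report
}

#' Serialize a study report to JSON
#'
#' @param report a `study_report`.
#' @param path output path.
#' @export
write_study_report <- function(report, path) {
  stopifnot(inherits(report, "study_report"))
  x <- list(
    optimum = as.list(report$optimization$optimum),
    pulse_number_rounded = report$optimization$pulse_number_rounded,
    desirability = report$optimization$desirability,
    predicted = as.list(report$optimization$predicted),
    anova = list(
      area = report$anova$area$factors,
      temperature = report$anova$temperature$factors),
    comparison = report$comparison,
    thermal_damage = report$thermal_damage)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(path)
}

#' @export
print.study_report <- function(x, ...) {
  o <- x$optimization$optimum
  cat("<study_report>\n")
  cat(sprintf("  optimum: AL %g mm, D %g mm, %g V, %.2f pulses (rounded %g), %.2f us\n",
              o[["active_length_mm"]], o[["distance_mm"]], o[["voltage_V"]],
              o[["pulse_number"]], x$optimization$pulse_number_rounded,
              o[["pulse_width_us"]]))
  cat(sprintf("  predicted: area %.2f mm^2, max T %.2f C\n",
              x$optimization$predicted[["area"]],
              x$optimization$predicted[["temperature"]]))
  if (!is.null(x$comparison)) {
    cat(sprintf("  verified:  area %.2f mm^2 (%.2f%% err), max T %.2f C (%.2f%% err)\n",
                x$comparison$models[1], x$comparison$error_pct[1],
                x$comparison$models[2], x$comparison$error_pct[2]))
  }
  invisible(x)
}
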