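# Scalar treatment responses: ablation area, peak temperature, damage flag.

#' Ablation area from a field-magnitude map
#'
#' Cell-counting integral of the region where |E| meets or exceeds the
#' lethal-electroporation threshold: (number of tissue nodes with
#' |E| >= threshold) x cell area. Electrode-interior nodes are excluded.
#' The default threshold is 800 V/cm = 8e4 V/m, the standard scale for
#' liver IRE.
#'
#' @param field a [field_magnitude()].
#' @param grid the simulation grid.
#' @param threshold lethal field threshold in V/m (> 0); default `8e4`.
#' @return area in mm^2.
#' @export
ablation_area <- function(field, grid, threshold = 8e4) {
  stopifnot(inherits(field, "field_magnitude"), inherits(grid, "ire_grid"))
  if (!is.finite(threshold) || threshold <= 0) stop("threshold must be positive")
  tis <- grid$region == REGION_TISSUE
  sum(field$E[tis] >= threshold) * cell_area_mm2(grid)
}

#' Thermal-damage verdict
#'
#' TRUE iff the maximum temperature over space and time reaches the damage
#' limit (boundary inclusive).
#'
#' @param sim an [ire_simulation][simulate_treatment()] object, or a numeric
#'   maximum temperature.
#' @param limit damage threshold in degrees C (default 50).
#' @return logical.
#' @export
thermal_damage_flag <- function(sim, limit = 50) {
  tmax <- if (inherits(sim, "ire_simulation")) sim$max_temperature else as.numeric(sim)
  if (!is.finite(tmax)) stop("maximum temperature must be finite")
  tmax >= limit
}

#' Reduce a simulation to its response record
#'
#' @param sim an [ire_simulation][simulate_treatment()].
#' @param protocol the protocol simulated (defaults to the one inside `sim`).
#' @param threshold ablation field threshold, V/m.
#' @param damage_limit thermal damage limit, degrees C.
#' @param run_id optional identifier.
#' @return one-row data.frame with the byte-stable column order
#'   run_id, active_length_mm, distance_mm, voltage_V, pulse_number,
#'   pulse_width_us, ablation_area_mm2, max_temperature_C, thermal_damage.
#' @export
response_record <- function(sim, protocol = sim$protocol, threshold = 8e4,
                            damage_limit = 50, run_id = NA_integer_) {
  stopifnot(inherits(sim, "ire_simulation"))
  el <- sim$grid$electrodes
  data.frame(run_id = run_id,
             active_length_mm = el$active_length,
             distance_mm = el$distance,
             voltage_V = el$voltage,
             pulse_number = protocol$pulse_number,
             pulse_width_us = protocol$pulse_width,
             ablation_area_mm2 = round(ablation_area(sim$field, sim$grid, threshold), 2),
             max_temperature_C = round(sim$max_temperature, 2),
             thermal_damage = thermal_damage_flag(sim, damage_limit))
}

RESPONSE_COLUMNS <- c("run_id", "active_length_mm", "distance_mm", "voltage_V",
                      "pulse_number", "pulse_width_us", "ablation_area_mm2",
                      "max_temperature_C", "thermal_damage")

#' Write / read a response table CSV
#'
#' Column order is fixed and the two responses are printed with exactly two
#' decimals (their reporting precision) so that pipeline outputs are
#' byte-stable and diff cleanly.
#' @param responses data.frame of response records.
#' @param path CSV path.
#' @export
write_response_table <- function(responses, path) {
  cols <- intersect(RESPONSE_COLUMNS, names(responses))
  out <- responses[, cols, drop = FALSE]
  for (cc in intersect(c("ablation_area_mm2", "max_temperature_C"), cols)) {
    fmt <- ifelse(is.na(out[[cc]]), "NA",
                  format(round(out[[cc]], 2), nsmall = 2, trim = TRUE,
                         scientific = FALSE))
    out[[cc]] <- fmt
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_response_table
#' @export
read_response_table <- function(path) {
  utils::read.csv(path)
}
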