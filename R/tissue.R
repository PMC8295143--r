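#' Piecewise-linear material property curve
#'
#' Material properties that vary with temperature or electric-field magnitude
#' are represented as piecewise-linear curves over an ordered set of knots.
#' Evaluation outside the knot range clamps to the endpoint values, which
#' guarantees that a conductivity curve can never extrapolate to a
#' non-physical (e.g. negative) value.
#'
#' @param x numeric vector of knot abscissae, strictly increasing.
#' @param value numeric vector of property values at the knots.
#' @param abscissa one of `"temperature"` (degrees C) or `"field_magnitude"`
#'   (V/m); recorded so curves cannot silently be used on the wrong axis.
#' @return an object of class `property_curve`.
#' @export
property_curve <- function(x, value, abscissa = c("temperature", "field_magnitude")) {
  abscissa <- match.arg(abscissa)
  if (length(x) != length(value) || length(x) < 1L)
    stop("'x' and 'value' must be non-empty vectors of equal length")
  if (anyNA(x) || anyNA(value) || any(!is.finite(x)) || any(!is.finite(value)))
    stop("curve knots must be finite")
  if (is.unsorted(x, strictly = TRUE))
    stop("knot abscissae must be strictly increasing")
  structure(list(x = as.numeric(x), value = as.numeric(value), abscissa = abscissa),
            class = "property_curve")
}

#' Evaluate a property curve
#'
#' Linear interpolation between knots; clamped to the first/last knot value
#' outside the knot range. Continuous everywhere.
#'
#' @param curve a [property_curve()].
#' @param at numeric vector of evaluation points.
#' @return numeric vector of property values.
#' @export
eval_curve <- function(curve, at) {
  stopifnot(inherits(curve, "property_curve"))
  if (anyNA(at) || any(!is.finite(at))) stop("evaluation points must be finite")
  if (length(curve$x) == 1L) return(rep(curve$value, length(at)))
  stats::approx(curve$x, curve$value, xout = at, rule = 2)$y
}

#' Read a property curve from a two-column CSV
#'
#' Expected format: header row `x,value`; `x` in SI units (V/m for field
#' curves, degrees C for temperature curves).
#'
#' @param path CSV file path.
#' @inheritParams property_curve
#' @export
read_property_curve <- function(path, abscissa = c("temperature", "field_magnitude")) {
  d <- utils::read.csv(path)
  if (!all(c("x", "value") %in% names(d)))
    stop("property-curve CSV must have columns 'x' and 'value'")
  property_curve(d$x, d$value, abscissa = match.arg(abscissa))
}

#' Tissue property set for the liver model
#'
#' Bundles the scalar constants (density, heat capacity) with the three
#' property curves: thermal conductivity k(T), relative permittivity
#' eps_r(T) and electrical conductivity sigma(|E|). The sigma curve is the
#' only material nonlinearity entering the electric problem; the
#' permittivity curve is carried for interface completeness but does not
#' enter the quasi-static (DC) solver.
#'
#' Defaults are the bovine-liver constants (density 1050 kg/m^3, heat
#' capacity 3400 J/(kg C)) with the curves shipped in `inst/extdata`:
#' sigma rising from 0.0650 S/m below 10 kV/m to 0.1483 S/m above 70 kV/m
#' along a symmetric smoothstep knot set, constant k = 0.52 W/(m C).
#'
#' @param density kg/m^3, positive.
#' @param heat_capacity J/(kg C), positive.
#' @param k_curve thermal conductivity curve (W/(m C) vs temperature).
#' @param sigma_curve electrical conductivity curve (S/m vs |E| in V/m).
#' @param epsr_curve relative permittivity curve (vs temperature); inert in
#'   the DC solver.
#' @return object of class `tissue_properties`.
#' @export
tissue_properties <- function(density = 1050, heat_capacity = 3400,
                              k_curve = NULL, sigma_curve = NULL, epsr_curve = NULL) {
  if (!is.finite(density) || density <= 0) stop("density must be positive")
  if (!is.finite(heat_capacity) || heat_capacity <= 0) stop("heat_capacity must be positive")
  ext <- function(f) system.file("extdata", f, package = "ireplan", mustWork = TRUE)
  if (is.null(k_curve)) k_curve <- read_property_curve(ext("k_vs_temperature.csv"), "temperature")
  if (is.null(sigma_curve)) sigma_curve <- read_property_curve(ext("sigma_vs_field.csv"), "field_magnitude")
  if (is.null(epsr_curve)) epsr_curve <- read_property_curve(ext("epsr_vs_temperature.csv"), "temperature")
  stopifnot(inherits(k_curve, "property_curve"), inherits(sigma_curve, "property_curve"),
            inherits(epsr_curve, "property_curve"))
  if (any(k_curve$value <= 0)) stop("thermal conductivity curve must be positive")
  if (is.unsorted(sigma_curve$value)) stop("sigma curve must be non-decreasing in |E|")
  if (any(sigma_curve$value < 0)) stop("sigma curve must be non-negative")
  structure(list(density = density, heat_capacity = heat_capacity,
                 k_curve = k_curve, sigma_curve = sigma_curve, epsr_curve = epsr_curve,
                 sigma_min = min(sigma_curve$value), sigma_max = max(sigma_curve$value)),
            class = "tissue_properties")
}

#' Electrical conductivity at a given field magnitude
#'
#' Clamped piecewise-linear evaluation of the sigma(|E|) curve; bounded by
#' the curve's floor and ceiling and non-decreasing in its argument.
#'
#' @param props a [tissue_properties()] object.
#' @param field_magnitude |E| in V/m, non-negative.
#' @return conductivity in S/m.
#' @export
sigma_of_field <- function(props, field_magnitude) {
  stopifnot(inherits(props, "tissue_properties"))
  if (anyNA(field_magnitude) || any(!is.finite(field_magnitude)))
    stop("field magnitude must be finite")
  if (any(field_magnitude < 0)) stop("field magnitude must be non-negative")
  eval_curve(props$sigma_curve, field_magnitude)
}

#' Thermal conductivity at a given temperature
#'
#' @param props a [tissue_properties()] object.
#' @param temperature degrees C; must be finite and within 0-120 C.
#' @return thermal conductivity in W/(m C).
#' @export
k_of_temperature <- function(props, temperature) {
  stopifnot(inherits(props, "tissue_properties"))
  if (anyNA(temperature) || any(!is.finite(temperature)))
    stop("temperature must be finite")
  if (any(temperature < 0) || any(temperature > 120))
    stop("temperature outside the plausible 0-120 C range")
  eval_curve(props$k_curve, temperature)
}

#' Relative permittivity at a given temperature (inert in the DC solver)
#' @inheritParams k_of_temperature
#' @export
epsr_of_temperature <- function(props, temperature) {
  stopifnot(inherits(props, "tissue_properties"))
  if (anyNA(temperature) || any(!is.finite(temperature)))
    stop("temperature must be finite")
  eval_curve(props$epsr_curve, temperature)
}

#' Blood/metabolism constants of the Pennes bioheat model
#'
#' Defaults: blood density 1000 kg/m^3, specific heat 3640 J/(kg C),
#' perfusion rate 5e-4 1/s, arterial temperature 37 C, zero metabolic heat.
#'
#' @param blood_density kg/m^3.
#' @param blood_heat_capacity J/(kg C).
#' @param perfusion_rate 1/s.
#' @param blood_temperature degrees C.
#' @param metabolic_heat W/m^3.
#' @return object of class `blood_constants`.
#' @export
blood_constants <- function(blood_density = 1000, blood_heat_capacity = 3640,
                            perfusion_rate = 5e-4, blood_temperature = 37,
                            metabolic_heat = 0) {
  v <- c(blood_density, blood_heat_capacity, perfusion_rate, metabolic_heat)
  if (anyNA(v) || any(!is.finite(v)) || any(v < 0))
    stop("blood constants must be finite and non-negative")
  if (!is.finite(blood_temperature)) stop("blood temperature must be finite")
  structure(list(blood_density = blood_density,
                 blood_heat_capacity = blood_heat_capacity,
                 perfusion_rate = perfusion_rate,
                 blood_temperature = blood_temperature,
                 metabolic_heat = metabolic_heat),
            class = "blood_constants")
}

#' Perfusion heat sink of the Pennes model
#'
#' Volumetric power rho_b * c_pb * omega_b * (T_b - T): zero at the arterial
#' temperature, negative (a sink) above it.
#'
#' @param blood a [blood_constants()] object.
#' @param temperature tissue temperature, degrees C.
#' @return volumetric power in W/m^3.
#' @export
perfusion_sink <- function(blood, temperature) {
  stopifnot(inherits(blood, "blood_constants"))
  if (anyNA(temperature) || any(!is.finite(temperature)))
    stop("temperature must be finite")
  blood$blood_density * blood$blood_heat_capacity * blood$perfusion_rate *
    (blood$blood_temperature - temperature)
}
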