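# Experimental-design generators: full factorial and the Taguchi L18 array.

#' Factor specification
#'
#' @param name factor name.
#' @param levels 2 or 3 strictly increasing numeric levels.
#' @param role `"discrete"` (settings restricted to the levels) or
#'   `"continuous"` (levels define the min/max of a continuous range).
#' @return object of class `factor_spec`.
#' @export
factor_spec <- function(name, levels, role = c("continuous", "discrete")) {
  role <- match.arg(role)
  if (!length(levels) %in% c(2L, 3L)) stop("a factor needs 2 or 3 levels")
  if (anyNA(levels) || any(!is.finite(levels))) stop("levels must be finite")
  if (is.unsorted(levels, strictly = TRUE)) stop("levels must be strictly increasing")
  structure(list(name = name, levels = as.numeric(levels), role = role),
            class = "factor_spec")
}

#' The five IRE study factors and their levels
#'
#' Active length 10/15 mm (2 levels, discrete hardware choice); electrode
#' distance 10/15/20 mm; voltage 1000/2000/3000 V; pulse number 30/60/90;
#' pulse width 40/70/100 us.
#'
#' @return named list of [factor_spec()] objects.
#' @export
default_factor_specs <- function() {
  list(
    active_length_mm = factor_spec("active_length_mm", c(10, 15), "discrete"),
    distance_mm      = factor_spec("distance_mm", c(10, 15, 20)),
    voltage_V        = factor_spec("voltage_V", c(1000, 2000, 3000)),
    pulse_number     = factor_spec("pulse_number", c(30, 60, 90)),
    pulse_width_us   = factor_spec("pulse_width_us", c(40, 70, 100))
  )
}

# linear map natural -> coded [-1, 1] based on the factor's min/max
#' Encode natural factor settings to coded units
#' @param value numeric vector of natural-unit settings.
#' @param spec a [factor_spec()].
#' @export
code_factor <- function(value, spec) {
  stopifnot(inherits(spec, "factor_spec"))
  lo <- spec$levels[1]; hi <- spec$levels[length(spec$levels)]
  2 * (value - lo) / (hi - lo) - 1
}

#' Decode coded units back to natural units
#' @param coded numeric vector in coded units.
#' @param spec a [factor_spec()].
#' @export
decode_factor <- function(coded, spec) {
  stopifnot(inherits(spec, "factor_spec"))
  lo <- spec$levels[1]; hi <- spec$levels[length(spec$levels)]
  lo + (coded + 1) / 2 * (hi - lo)
}

#' Full-factorial design
#'
#' Cartesian product of all factor levels, lexicographic order (last factor
#' varies fastest).
#'
#' @param specs list of [factor_spec()] objects.
#' @return data.frame with one column per factor plus `run_id`.
#' @export
full_factorial <- function(specs = default_factor_specs()) {
  if (length(specs) == 0) stop("empty factor specification")
  stopifnot(all(vapply(specs, inherits, logical(1), "factor_spec")))
  lv <- lapply(rev(specs), function(s) s$levels)
  d <- rev(expand.grid(lv, KEEP.OUT.ATTRS = FALSE))
  names(d) <- vapply(specs, function(s) s$name, character(1))
  cbind(run_id = seq_len(nrow(d)), d)
}

# The canonical L18(2^1 3^7) orthogonal array, columns 1-5 (1-based levels).
.L18_BASE <- matrix(c(
  1, 1, 1, 1, 1,
  1, 1, 2, 2, 2,
  1, 1, 3, 3, 3,
  1, 2, 1, 1, 2,
  1, 2, 2, 2, 3,
  1, 2, 3, 3, 1,
  1, 3, 1, 2, 1,
  1, 3, 2, 3, 2,
  1, 3, 3, 1, 3,
  2, 1, 1, 3, 3,
  2, 1, 2, 1, 1,
  2, 1, 3, 2, 2,
  2, 2, 1, 2, 3,
  2, 2, 2, 3, 1,
  2, 2, 3, 1, 2,
  2, 3, 1, 3, 2,
  2, 3, 2, 1, 3,
  2, 3, 3, 2, 1), nrow = 18, byrow = TRUE)

#' Taguchi L18 screening design
#'
#' Maps one 2-level factor and four 3-level factors onto the first five
#' columns of the standard L18(2^1 3^7) orthogonal array. Every level of
#' every factor appears equally often (9 times for the 2-level factor,
#' 6 times for each 3-level factor).
#'
#' @param specs list of exactly five [factor_spec()] objects: one with two
#'   levels first, then four with three levels.
#' @return data.frame with `run_id` and one column per factor.
#' @export
taguchi_L18 <- function(specs = default_factor_specs()) {
  stopifnot(all(vapply(specs, inherits, logical(1), "factor_spec")))
  nlev <- vapply(specs, function(s) length(s$levels), integer(1))
  if (length(specs) != 5L || nlev[1] != 2L || any(nlev[-1] != 3L))
    stop("the L18 mapping needs one 2-level factor followed by four 3-level factors")
  d <- as.data.frame(lapply(seq_along(specs), function(k)
    specs[[k]]$levels[.L18_BASE[, k]]))
  names(d) <- vapply(specs, function(s) s$name, character(1))
  cbind(run_id = 1:18, d)
}

#' Coded design matrix for a design table
#'
#' @param design data.frame with natural-unit factor columns.
#' @param specs matching list of [factor_spec()] objects.
#' @return data.frame of coded settings (same column names).
#' @export
code_design <- function(design, specs = default_factor_specs()) {
  nm <- vapply(specs, function(s) s$name, character(1))
  if (!all(nm %in% names(design))) stop("design is missing factor columns")
  out <- design[nm]
  for (k in seq_along(specs)) out[[k]] <- code_factor(design[[nm[k]]], specs[[k]])
  out
}
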