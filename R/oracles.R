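# Analytic oracles and synthetic-response generators used to verify the
# numerical solvers and the statistics stack. These share no numerical
# kernels with the code they check.

#' Two-wire (bipolar line-source) analytic potential
#'
#' Closed-form potential of two infinite parallel cylindrical conductors of
#' radius `a` at separation `d` (center-to-center), one held at `voltage`,
#' the other at 0, in the thin-wire limit a << d:
#'
#'   V(p) = V0/2 + V0/(2 ln(d/a)) * ln(r2/r1)
#'
#' where r1, r2 are the distances from p to the energized and grounded
#' axes. Exact for line charges; the cylinder surfaces are equipotential
#' only to O(a/d), so solver comparisons are restricted to a mid-plane band
#' away from the conductors.
#'
#' @param x,y evaluation coordinates (m), vectors of equal length.
#' @param center_hot c(x, y) of the energized conductor axis (m).
#' @param center_gnd c(x, y) of the grounded conductor axis (m).
#' @param radius conductor radius a (m).
#' @param voltage applied voltage V0.
#' @return potential values (V).
#' @export
two_wire_potential <- function(x, y, center_hot, center_gnd, radius, voltage) {
  d <- sqrt(sum((center_hot - center_gnd)^2))
  if (radius <= 0 || radius >= d / 2) stop("need 0 < radius << separation")
  r1 <- sqrt((x - center_hot[1])^2 + (y - center_hot[2])^2)
  r2 <- sqrt((x - center_gnd[1])^2 + (y - center_gnd[2])^2)
  if (any(r1 < 1e-12) || any(r2 < 1e-12))
    stop("evaluation point lies on a conductor axis (singular)")
  voltage / 2 + voltage / (2 * log(d / radius)) * log(r2 / r1)
}

#' Analytic field magnitude of the two-wire potential
#'
#' Gradient magnitude of [two_wire_potential()], obtained by analytic
#' differentiation (not finite differences).
#'
#' @inheritParams two_wire_potential
#' @return |E| values (V/m).
#' @export
two_wire_field <- function(x, y, center_hot, center_gnd, radius, voltage) {
  d <- sqrt(sum((center_hot - center_gnd)^2))
  if (radius <= 0 || radius >= d / 2) stop("need 0 < radius << separation")
  r1sq <- (x - center_hot[1])^2 + (y - center_hot[2])^2
  r2sq <- (x - center_gnd[1])^2 + (y - center_gnd[2])^2
  if (any(r1sq < 1e-24) || any(r2sq < 1e-24))
    stop("evaluation point lies on a conductor axis (singular)")
  k <- voltage / (2 * log(d / radius))
  gx <- (x - center_gnd[1]) / r2sq - (x - center_hot[1]) / r1sq
  gy <- (y - center_gnd[2]) / r2sq - (y - center_hot[2]) / r1sq
  k * sqrt(gx^2 + gy^2)
}

#' Synthetic quadratic responses for parameter-recovery tests
#'
#' Generates `response = quadratic(coded settings) + N(0, sd)` for every
#' row of a design, from a known coefficient set. With zero noise the
#' response-surface fit must recover the coefficients exactly.
#'
#' @param design natural-unit design table.
#' @param coef named list: `intercept` (scalar), `linear` (named vector,
#'   one entry per factor), `quad` (named vector over the 3-level factors).
#' @param specs factor specs.
#' @param noise_sd Gaussian noise standard deviation (default 0).
#' @param seed RNG seed.
#' @param response name of the generated column (default "y").
#' @return data.frame with the single response column.
#' @export
generate_synthetic_responses <- function(design, coef, specs = default_factor_specs(),
                                         noise_sd = 0, seed = 1, response = "y") {
  X <- code_design(design, specs)
  nm <- names(X)
  if (!all(names(coef$linear) %in% nm)) stop("unknown factor in linear coefficients")
  y <- rep(coef$intercept, nrow(X))
  for (f in names(coef$linear)) y <- y + coef$linear[[f]] * X[[f]]
  for (f in names(coef$quad)) y <- y + coef$quad[[f]] * X[[f]]^2
  if (noise_sd > 0) {
    set.seed(seed)
    y <- y + stats::rnorm(length(y), 0, noise_sd)
  }
  stats::setNames(data.frame(y), response)
}
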