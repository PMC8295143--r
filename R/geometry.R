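#' Electrode pair configuration
#'
#' Two identical parallel needle electrodes inserted vertically from the
#' tissue surface. The modeling plane contains both electrode axes, so the
#' active (conductive) segment of each needle appears as a rectangle of
#' `diameter` x `active_length` ending at the tip, with the insulated shaft
#' above it. All lengths in mm (clinician units); converted to SI internally.
#'
#' @param active_length mm, exposed conductive length (> 0).
#' @param distance mm, center-to-center electrode separation.
#' @param voltage V, potential applied between the electrodes (>= 0).
#' @param diameter mm, needle diameter (default 1.0 mm, typical 18-19 G).
#' @param insertion_depth mm, tissue surface to electrode tip (default 20).
#' @return object of class `electrode_config`.
#' @export
electrode_config <- function(active_length, distance, voltage,
                             diameter = 1.0, insertion_depth = 20) {
  v <- c(active_length, distance, voltage, diameter, insertion_depth)
  if (anyNA(v) || any(!is.finite(v))) stop("electrode parameters must be finite")
  if (active_length <= 0) stop("active_length must be positive")
  if (voltage < 0) stop("voltage must be non-negative")
  if (distance <= diameter)
    stop("electrodes overlap: distance must exceed the diameter")
  if (active_length > insertion_depth)
    stop("active_length cannot exceed insertion_depth")
  structure(list(active_length = active_length, distance = distance,
                 voltage = voltage, diameter = diameter,
                 insertion_depth = insertion_depth),
            class = "electrode_config")
}

#' Simulation domain specification
#'
#' A rectangle of tissue, insulated (both electrically and thermally) at its
#' outer boundary, discretized on a uniform node lattice. x runs to the
#' right, y downward from the tissue surface. The default 60 x 60 mm extent
#' keeps the insulated boundary far enough from the electrodes that it
#' perturbs the near-field by well under a percent (checked by the
#' domain-doubling test).
#'
#' @param width,height mm.
#' @param spacing mm, uniform grid spacing; must divide width and height.
#' @param margin mm, minimum clearance required between any electrode node
#'   and the lateral/bottom boundary (default 15).
#' @return object of class `domain_spec`.
#' @export
domain_spec <- function(width = 60, height = 60, spacing = 0.25, margin = 15) {
  v <- c(width, height, spacing, margin)
  if (anyNA(v) || any(!is.finite(v)) || any(v[1:3] <= 0))
    stop("domain dimensions must be positive and finite")
  divides <- function(a, s) abs(a / s - round(a / s)) < 1e-9
  if (!divides(width, spacing) || !divides(height, spacing))
    stop("spacing must divide both width and height")
  structure(list(width = width, height = height, spacing = spacing,
                 margin = margin), class = "domain_spec")
}

# region codes used throughout the solvers
REGION_TISSUE <- 0L
REGION_LEFT_ACTIVE <- 1L
REGION_RIGHT_ACTIVE <- 2L
REGION_SHAFT <- 3L

#' Build the structured simulation grid
#'
#' Places the two electrodes symmetrically about the vertical domain
#' centerline and labels every node as tissue, left/right active electrode,
#' or insulated shaft. The center measurement point is the node nearest the
#' midpoint between the electrode axes at half the active length above the
#' tip.
#'
#' @param domain a [domain_spec()].
#' @param electrodes an [electrode_config()].
#' @return object of class `ire_grid` with fields `nx`, `ny`, `h` (m),
#'   `x`, `y` (node coordinates in m), `region` (nx x ny integer matrix),
#'   `center_ij` (c(i, j) node index), plus the input specs.
#' @export
build_grid <- function(domain, electrodes) {
  stopifnot(inherits(domain, "domain_spec"), inherits(electrodes, "electrode_config"))
  mm <- 1e-3
  h <- domain$spacing * mm
  if (domain$spacing > electrodes$diameter)
    stop("grid spacing is coarser than the electrode diameter")
  nx <- round(domain$width / domain$spacing) + 1L
  ny <- round(domain$height / domain$spacing) + 1L
  x <- (seq_len(nx) - 1L) * h
  y <- (seq_len(ny) - 1L) * h
  xc_l <- (domain$width / 2 - electrodes$distance / 2) * mm
  xc_r <- (domain$width / 2 + electrodes$distance / 2) * mm
  rad <- electrodes$diameter / 2 * mm
  tip <- electrodes$insertion_depth * mm
  top_active <- tip - electrodes$active_length * mm

  if (xc_l - rad < domain$margin * mm - 1e-12 ||
      xc_r + rad > (domain$width - domain$margin) * mm + 1e-12 ||
      tip > (domain$height - domain$margin) * mm + 1e-12)
    stop("electrodes (plus margin) do not fit inside the domain")

  tol <- 1e-9
  in_l <- abs(x - xc_l) <= rad + tol
  in_r <- abs(x - xc_r) <= rad + tol
  y_active <- y >= top_active - tol & y <= tip + tol
  y_shaft <- y < top_active - tol
  region <- matrix(REGION_TISSUE, nx, ny)
  region[in_l, y_active] <- REGION_LEFT_ACTIVE
  region[in_r, y_active] <- REGION_RIGHT_ACTIVE
  region[in_l, y_shaft] <- REGION_SHAFT
  region[in_r, y_shaft] <- REGION_SHAFT
  if (!any(region == REGION_LEFT_ACTIVE) || !any(region == REGION_RIGHT_ACTIVE))
    stop("active electrode masks are empty; refine the grid")

  center <- c(which.min(abs(x - (xc_l + xc_r) / 2)),
              which.min(abs(y - (tip - electrodes$active_length * mm / 2))))
  structure(list(nx = nx, ny = ny, h = h, x = x, y = y, region = region,
                 center_ij = center, domain = domain, electrodes = electrodes),
            class = "ire_grid")
}

#' Outer temperature-probe location
#'
#' Node nearest to 3 mm laterally outward of the right electrode surface at
#' the depth of the electrode tip (the placement used for the outer
#' fiber-optic probe in the validation experiments).
#'
#' @param grid an [ire_grid][build_grid()].
#' @param offset mm from the electrode surface (default 3).
#' @return c(i, j) node index.
#' @export
outer_probe_point <- function(grid, offset = 3) {
  stopifnot(inherits(grid, "ire_grid"))
  mm <- 1e-3
  el <- grid$electrodes
  xs <- (grid$domain$width / 2 + el$distance / 2 + el$diameter / 2 + offset) * mm
  yt <- el$insertion_depth * mm
  if (xs > max(grid$x) + 1e-12) stop("outer probe point lies outside the domain")
  c(which.min(abs(grid$x - xs)), which.min(abs(grid$y - yt)))
}

#' @export
print.ire_grid <- function(x, ...) {
  cat(sprintf("<ire_grid> %d x %d nodes, spacing %g mm\n", x$nx, x$ny, x$h * 1e3))
  cat(sprintf("  electrodes: active %g mm, distance %g mm, diameter %g mm, %g V\n",
              x$electrodes$active_length, x$electrodes$distance,
              x$electrodes$diameter, x$electrodes$voltage))
  invisible(x)
}

# cell area in mm^2
cell_area_mm2 <- function(grid) (grid$h * 1e3)^2
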