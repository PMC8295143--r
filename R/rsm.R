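# Quadratic response-surface fitting, ANOVA and desirability optimization.

#' Fit a quadratic response surface on coded units
#'
#' Ordinary least squares of `response` on the coded factor settings:
#' intercept, a linear term for every factor and a pure quadratic term for
#' every 3-level factor. Two-factor interactions are not estimable with an
#' 18-run screening array on top of this term set and are excluded by
#' default; `interactions = TRUE` adds them in a fixed lexicographic order,
#' pruning from the highest-order end until the design matrix has full
#' rank.
#'
#' @param design data.frame with natural-unit factor columns (plus anything
#'   else, e.g. `run_id`).
#' @param responses data.frame aligned row-for-row with `design`.
#' @param response name of the response column in `responses`.
#' @param specs list of [factor_spec()] objects.
#' @param interactions logical, see above.
#' @return object of class `ire_rsm`.
#' @export
fit_rsm <- function(design, responses, response, specs = default_factor_specs(),
                    interactions = FALSE) {
  if (nrow(design) != nrow(responses)) stop("design and responses are not aligned")
  if (!response %in% names(responses)) stop("unknown response column: ", response)
  X <- code_design(design, specs)
  y <- responses[[response]]
  if (anyNA(y)) stop("missing response values")
  nm <- names(X)
  quad <- nm[vapply(specs, function(s) length(s$levels) == 3L, logical(1))]
  terms <- c(nm, paste0("I(", quad, "^2)"))
  if (interactions) {
    pairs <- utils::combn(nm, 2, function(p) paste(p, collapse = ":"))
    terms <- c(terms, pairs)
  }
  # prune from the end (highest-order terms first) until full rank
  repeat {
    f <- stats::as.formula(paste("y ~", paste(terms, collapse = " + ")))
    mm <- stats::model.matrix(f, data = X)
    if (qr(mm)$rank == ncol(mm) && nrow(mm) >= ncol(mm)) break
    if (length(terms) <= length(nm)) stop("fewer rows than intercept plus linear terms")
    terms <- terms[-length(terms)]
  }
  if (nrow(X) < length(terms) + 1L) stop("fewer rows than model terms")
  fit <- stats::lm(f, data = cbind(y = y, X))
  structure(list(fit = fit, specs = specs, response = response,
                 terms = terms, factor_names = nm,
                 y_range = range(y), data = cbind(y = y, X)),
            class = "ire_rsm")
}

#' Predict from a fitted response surface
#'
#' @param object an [ire_rsm][fit_rsm()].
#' @param newdata data.frame of natural-unit factor settings, or a named
#'   numeric vector for a single point.
#' @param coded set TRUE if `newdata` is already in coded units.
#' @param ... unused.
#' @export
predict.ire_rsm <- function(object, newdata, coded = FALSE, ...) {
  if (is.numeric(newdata) && !is.data.frame(newdata))
    newdata <- as.data.frame(as.list(newdata))
  X <- if (coded) newdata[object$factor_names] else code_design(newdata, object$specs)
  as.numeric(stats::predict(object$fit, newdata = X))
}

#' Per-term ANOVA of a response surface
#'
#' Reports the OLS t-test p-value of every model term against the residual
#' error. A factor is flagged significant when its linear term is
#' significant at `alpha`; this is the convention under which the printed
#' screening-study p-values are reproduced.
#'
#' @param model an [ire_rsm][fit_rsm()].
#' @param alpha significance level (default 0.05).
#' @return list with `terms` (data.frame term, estimate, std_error, p_value)
#'   and `factors` (data.frame factor, p_value, significant).
#' @export
rsm_anova <- function(model, alpha = 0.05) {
  stopifnot(inherits(model, "ire_rsm"))
  cf <- stats::summary.lm(model$fit)$coefficients
  terms <- data.frame(term = rownames(cf), estimate = cf[, 1],
                      std_error = cf[, 2], p_value = cf[, 4],
                      row.names = NULL)
  lin <- terms[match(model$factor_names, terms$term), ]
  factors <- data.frame(factor = model$factor_names,
                        p_value = lin$p_value,
                        significant = lin$p_value < alpha,
                        row.names = NULL)
  list(terms = terms, factors = factors, alpha = alpha,
       residual_df = model$fit$df.residual)
}

#' Desirability specification
#'
#' The composite objective follows the study's stated goal: maximize the
#' electric field between the electrodes while keeping the tissue at or
#' below the thermal-damage cap, with the predicted ablation area as a
#' third larger-is-better response. Per-response desirabilities:
#'
#' * area: linear ramp from `area_range[1]` (d = 0) to `area_range[2]`
#'   (d = 1); defaults to the observed response range.
#' * temperature, shape `"budget"` (default): ramp (T - temp_lo) /
#'   (temp_cap - temp_lo) for T <= cap — reward using the full thermal
#'   budget — and d = 0 above the cap (hard damage constraint).
#'   Shape `"upper_bound"`: d = 1 at or below `temp_lo`, falling linearly
#'   to 0 at the cap (a pure stay-cool penalty).
#' * field (optional): larger-is-better ramp of the mean inter-electrode
#'   field V/distance over its achievable range.
#'
#' The composite is the geometric mean of the active desirabilities.
#'
#' @param area_range length-2 numeric or NULL (use observed range).
#' @param temp_cap thermal damage cap, degrees C (default 50).
#' @param temp_lo lower temperature anchor (default 37).
#' @param temp_shape `"budget"` or `"upper_bound"`.
#' @param include_field include the V/distance field-proxy desirability.
#' @return object of class `desirability_spec`.
#' @export
desirability_spec <- function(area_range = NULL, temp_cap = 50, temp_lo = 37,
                              temp_shape = c("budget", "upper_bound"),
                              include_field = TRUE) {
  temp_shape <- match.arg(temp_shape)
  if (temp_lo >= temp_cap) stop("temp_lo must be below temp_cap")
  structure(list(area_range = area_range, temp_cap = temp_cap, temp_lo = temp_lo,
                 temp_shape = temp_shape, include_field = include_field),
            class = "desirability_spec")
}

.clamp01 <- function(x) pmin(pmax(x, 0), 1)

#' Composite desirability at natural-unit settings
#'
#' @param area predicted ablation area, mm^2.
#' @param temperature predicted maximum temperature, degrees C.
#' @param dspec a [desirability_spec()].
#' @param area_range resolved area anchors (lo, hi).
#' @param field mean inter-electrode field V/m (required when the field
#'   desirability is active).
#' @param field_range achievable field range (lo, hi), V/m.
#' @return composite desirability in `[0, 1]`.
#' @export
composite_desirability <- function(area, temperature, dspec, area_range,
                                   field = NULL, field_range = NULL) {
  dA <- .clamp01((area - area_range[1]) / diff(area_range))
  dT <- if (dspec$temp_shape == "budget") {
    ifelse(temperature > dspec$temp_cap, 0,
           .clamp01((temperature - dspec$temp_lo) / (dspec$temp_cap - dspec$temp_lo)))
  } else {
    .clamp01((dspec$temp_cap - temperature) / (dspec$temp_cap - dspec$temp_lo))
  }
  if (dspec$include_field) {
    if (is.null(field) || is.null(field_range))
      stop("field desirability requested but no field value/range supplied")
    dF <- .clamp01((field - field_range[1]) / diff(field_range))
    (dA * dT * dF)^(1 / 3)
  } else {
    sqrt(dA * dT)
  }
}

# internal: compile a fitted surface into a direct polynomial evaluator in
# a fixed factor order (avoids stats::predict overhead inside optimization
# loops). Returns function(x) with x a numeric vector ordered as `order`.
.rsm_evaluator <- function(model, order = model$factor_names) {
  cf <- stats::coef(model$fit)
  nms <- names(cf)
  nf <- length(order)
  c0 <- 0; lin <- numeric(nf); quad <- numeric(nf)
  inter_i <- integer(0); inter_j <- integer(0); inter_c <- numeric(0)
  for (k in seq_along(cf)) {
    nm <- nms[k]
    if (nm == "(Intercept)") { c0 <- cf[[k]]; next }
    m <- regmatches(nm, regexec("^I\\((.+)\\^2\\)$", nm))[[1]]
    if (length(m) == 2) { quad[match(m[2], order)] <- cf[[k]]; next }
    if (grepl(":", nm, fixed = TRUE)) {
      pr <- strsplit(nm, ":", fixed = TRUE)[[1]]
      inter_i <- c(inter_i, match(pr[1], order))
      inter_j <- c(inter_j, match(pr[2], order))
      inter_c <- c(inter_c, cf[[k]])
      next
    }
    lin[match(nm, order)] <- cf[[k]]
  }
  if (length(inter_c)) {
    function(x) c0 + sum(lin * x) + sum(quad * x * x) +
      sum(inter_c * x[inter_i] * x[inter_j])
  } else {
    function(x) c0 + sum(lin * x) + sum(quad * x * x)
  }
}

# internal: evaluate the composite on coded coordinates (named list/df)
.composite_on_coded <- function(coded, models, dspec, specs, area_range, field_range) {
  A <- predict.ire_rsm(models$area, coded, coded = TRUE)
  Tm <- predict.ire_rsm(models$temperature, coded, coded = TRUE)
  fld <- NULL
  if (dspec$include_field) {
    d_mm <- decode_factor(coded[["distance_mm"]], specs$distance_mm)
    v_V <- decode_factor(coded[["voltage_V"]], specs$voltage_V)
    fld <- v_V / (d_mm * 1e-3)
  }
  composite_desirability(A, Tm, dspec, area_range, fld, field_range)
}

#' Desirability-optimal protocol from fitted response surfaces
#'
#' Enumerates the 2-level (discrete hardware) factor and, within each
#' slice, maximizes the composite desirability over the continuous coded
#' cube of the remaining factors by multi-start Nelder-Mead (a coarse grid
#' seeds half the starts; the rest are drawn uniformly under a fixed seed).
#' Coordinates converging within 1e-4 of a box corner are snapped to it and
#' the interior coordinates re-polished.
#'
#' Slice selection: the discrete factor is chosen by composite desirability
#' only if it is significant (at `alpha`) in at least one response model;
#' when it is statistically inert in both, the lower (less invasive) level
#' is preferred, since the slice ranking would otherwise rest on noise.
#' Exact desirability ties are broken toward the smallest voltage, then the
#' smallest pulse number.
#'
#' @param models list with elements `area` and `temperature`, both
#'   [ire_rsm][fit_rsm()] fits on the same factor specs.
#' @param dspec a [desirability_spec()].
#' @param specs factor specifications (defaults to the models').
#' @param n_starts number of local searches per slice (default 64).
#' @param seed RNG seed for the random starts (default 1).
#' @param alpha significance level for the slice-selection rule.
#' @return list with `optimum` (named natural-unit settings),
#'   `optimum_coded`, `predicted` (area, temperature), `desirability`,
#'   `pulse_number_rounded` (nearest multiple of 10), and `slices` (the
#'   per-level results).
#' @export
optimize_desirability <- function(models, dspec = desirability_spec(),
                                  specs = NULL, n_starts = 64, seed = 1,
                                  alpha = 0.05) {
  stopifnot(inherits(models$area, "ire_rsm"), inherits(models$temperature, "ire_rsm"),
            inherits(dspec, "desirability_spec"))
  if (is.null(specs)) specs <- models$area$specs
  nm <- vapply(specs, function(s) s$name, character(1))
  names(specs) <- nm
  nlev <- vapply(specs, function(s) length(s$levels), integer(1))
  disc <- nm[nlev == 2L]
  cont <- nm[nlev != 2L]
  if (length(disc) != 1L) stop("expected exactly one 2-level factor")
  area_range <- if (is.null(dspec$area_range)) models$area$y_range else dspec$area_range
  if (diff(area_range) <= 0) stop("degenerate area desirability range")
  field_range <- NULL
  if (dspec$include_field) {
    dlv <- specs$distance_mm$levels; vlv <- specs$voltage_V$levels
    field_range <- c(min(vlv) / (max(dlv) * 1e-3), max(vlv) / (min(dlv) * 1e-3))
  }
  eval_area <- .rsm_evaluator(models$area, nm)
  eval_temp <- .rsm_evaluator(models$temperature, nm)
  d_idx <- match("distance_mm", cont)
  v_idx <- match("voltage_V", cont)
  disc_pos <- match(disc, nm)
  cont_pos <- match(cont, nm)
  v_lo <- specs$voltage_V$levels[1]
  v_hi <- specs$voltage_V$levels[length(specs$voltage_V$levels)]
  dm_lo <- specs$distance_mm$levels[1]
  dm_hi <- specs$distance_mm$levels[length(specs$distance_mm$levels)]
  objective <- function(p, a_coded) {
    p <- pmin(pmax(p, -1), 1)
    x <- numeric(length(nm))
    x[disc_pos] <- a_coded
    x[cont_pos] <- p
    A <- eval_area(x)
    Tm <- eval_temp(x)
    fld <- NULL
    if (dspec$include_field) {
      vv <- v_lo + (p[v_idx] + 1) / 2 * (v_hi - v_lo)
      dd <- dm_lo + (p[d_idx] + 1) / 2 * (dm_hi - dm_lo)
      fld <- vv / (dd * 1e-3)
    }
    composite_desirability(A, Tm, dspec, area_range, fld, field_range)
  }

  set.seed(seed)
  slices <- list()
  for (a_lv in c(-1, 1)) {
    # seed starts: coarse grid top points plus uniform draws
    g <- seq(-1, 1, length.out = 7)
    G <- as.matrix(expand.grid(rep(list(g), length(cont))))
    gv <- apply(G, 1, objective, a_coded = a_lv)
    ord <- order(gv, decreasing = TRUE)
    n_grid <- min(ceiling(n_starts / 2), nrow(G))
    starts <- rbind(G[ord[seq_len(n_grid)], , drop = FALSE],
                    matrix(stats::runif((n_starts - n_grid) * length(cont), -1, 1),
                           ncol = length(cont)))
    best <- NULL
    for (r in seq_len(nrow(starts))) {
      o <- stats::optim(starts[r, ], function(p) -objective(p, a_lv),
                        method = "Nelder-Mead",
                        control = list(reltol = 1e-10, maxit = 800))
      if (is.null(best) || -o$value > best$value + 1e-12) {
        best <- list(par = pmin(pmax(o$par, -1), 1), value = -o$value)
      }
    }
    # snap near-corner coordinates and re-polish the remaining ones
    p <- best$par
    at_corner <- abs(abs(p) - 1) < 1e-4
    p[at_corner] <- sign(p[at_corner])
    if (any(!at_corner)) {
      free <- which(!at_corner)
      fr_obj <- function(q) { pp <- p; pp[free] <- q; -objective(pp, a_lv) }
      o <- if (length(free) > 1) {
        stats::optim(p[free], fr_obj, method = "Nelder-Mead",
                     control = list(reltol = 1e-10, maxit = 800))
      } else {
        stats::optim(p[free], fr_obj, method = "Brent", lower = -1, upper = 1)
      }
      if (-o$value >= best$value) {
        p[free] <- pmin(pmax(o$par, -1), 1)
        best$value <- -o$value
      }
    }
    coded <- c(stats::setNames(a_lv, disc), stats::setNames(p, cont))
    nat <- vapply(nm, function(f) decode_factor(coded[[f]], specs[[f]]), numeric(1))
    slices[[length(slices) + 1L]] <- list(
      level = decode_factor(a_lv, specs[[disc]]), coded = coded,
      natural = nat, desirability = best$value,
      predicted = c(area = predict.ire_rsm(models$area, as.data.frame(as.list(coded)), coded = TRUE),
                    temperature = predict.ire_rsm(models$temperature, as.data.frame(as.list(coded)), coded = TRUE)))
  }
  if (all(vapply(slices, function(s) s$desirability <= 0, logical(1))))
    stop("composite desirability is zero everywhere; check the models and anchors")

  # a noiseless (interpolating) fit has no residual df: its p-values are
  # undefined and the factor is treated as not established as significant
  p_area <- suppressWarnings(rsm_anova(models$area, alpha)$factors)
  p_temp <- suppressWarnings(rsm_anova(models$temperature, alpha)$factors)
  disc_sig <- isTRUE(p_area$significant[p_area$factor == disc]) ||
    isTRUE(p_temp$significant[p_temp$factor == disc])
  pick <- if (disc_sig) {
    vals <- vapply(slices, function(s) s$desirability, numeric(1))
    # tie-break: smaller voltage, then smaller pulse number
    ord <- order(-vals,
                 vapply(slices, function(s) s$natural[["voltage_V"]], numeric(1)),
                 vapply(slices, function(s) s$natural[["pulse_number"]], numeric(1)))
    ord[1]
  } else 1L  # lower level listed first
  sel <- slices[[pick]]
  list(optimum = sel$natural, optimum_coded = sel$coded,
       predicted = sel$predicted, desirability = sel$desirability,
       pulse_number_rounded = round(sel$natural[["pulse_number"]] / 10) * 10,
       discrete_factor = disc, discrete_significant = disc_sig,
       area_range = area_range, field_range = field_range,
       slices = slices)
}

#' Main-effects table of a screening study
#'
#' Mean response at every level of every factor — the tabular analogue of
#' the factorial-trend plots used to read off how each parameter pushes the
#' responses.
#'
#' @param design natural-unit design table.
#' @param responses aligned response table.
#' @param response response column name.
#' @param specs factor specs.
#' @return data.frame with columns factor, level, mean_response.
#' @export
main_effects <- function(design, responses, response, specs = default_factor_specs()) {
  if (!response %in% names(responses)) stop("unknown response column: ", response)
  nm <- vapply(specs, function(s) s$name, character(1))
  out <- do.call(rbind, lapply(nm, function(f) {
    m <- tapply(responses[[response]], design[[f]], mean)
    data.frame(factor = f, level = as.numeric(names(m)), mean_response = as.numeric(m))
  }))
  rownames(out) <- NULL
  out
}
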