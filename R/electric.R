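# Quasi-static electric solver on the structured grid.
#
# Discretization: node-centered finite volumes with a 5-point stencil.
# Unknowns are the tissue nodes; active-electrode nodes carry Dirichlet
# values (applied voltage on the left electrode, 0 on the right), the
# insulated shaft and the outer boundary are zero-flux. Face conductivity
# is the mean of the adjacent tissue-node conductivities (the electrode is
# a perfect conductor, so a face touching it uses the tissue-side value).

# internal: conductivity field at tissue nodes given |E| (NA elsewhere)
.node_sigma <- function(grid, props, Emag) {
  sig <- matrix(NA_real_, grid$nx, grid$ny)
  tis <- grid$region == REGION_TISSUE
  sig[tis] <- sigma_of_field(props, Emag[tis])
  sig
}

# internal: assemble the conservation system A V = b for current sigma field
.assemble_electric <- function(grid, sig, voltage) {
  nx <- grid$nx; ny <- grid$ny
  region <- grid$region
  unknown <- region == REGION_TISSUE
  num <- matrix(0L, nx, ny)
  num[unknown] <- seq_len(sum(unknown))
  nun <- sum(unknown)
  dval <- matrix(NA_real_, nx, ny)
  dval[region == REGION_LEFT_ACTIVE] <- voltage
  dval[region == REGION_RIGHT_ACTIVE] <- 0

  ii <- jj <- integer(0); xx <- numeric(0)
  diag_acc <- numeric(nun); rhs <- numeric(nun)
  shifts <- list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))
  for (s in shifts) {
    di <- s[1]; dj <- s[2]
    ip <- seq_len(nx); jp <- seq_len(ny)
    ipr <- ip[ip + di >= 1L & ip + di <= nx]
    jpr <- jp[jp + dj >= 1L & jp + dj <= ny]
    P <- as.matrix(expand.grid(i = ipr, j = jpr))
    Q <- cbind(P[, 1] + di, P[, 2] + dj)
    pidx <- P[, 1] + (P[, 2] - 1L) * nx
    qidx <- Q[, 1] + (Q[, 2] - 1L) * nx
    keep <- unknown[pidx] & region[qidx] != REGION_SHAFT
    pidx <- pidx[keep]; qidx <- qidx[keep]
    sp <- sig[pidx]; sq <- sig[qidx]
    sf <- ifelse(is.na(sq), sp, (sp + sq) / 2)  # electrode face: tissue value
    pn <- num[pidx]
    qun <- unknown[qidx]
    # interior face to another unknown
    if (any(qun)) {
      ii <- c(ii, pn[qun]); jj <- c(jj, num[qidx[qun]]); xx <- c(xx, -sf[qun])
    }
    # face to a Dirichlet node contributes to the RHS
    dir <- !qun
    if (any(dir)) {
      add <- rowsum(sf[dir] * dval[qidx[dir]], pn[dir])
      rhs[as.integer(rownames(add))] <- rhs[as.integer(rownames(add))] + add[, 1]
    }
    addd <- rowsum(sf, pn)
    diag_acc[as.integer(rownames(addd))] <- diag_acc[as.integer(rownames(addd))] + addd[, 1]
  }
  A <- Matrix::sparseMatrix(i = c(ii, seq_len(nun)), j = c(jj, seq_len(nun)),
                            x = c(xx, diag_acc), dims = c(nun, nun))
  list(A = A, b = rhs, num = num, unknown = unknown, dval = dval)
}

#' Solve the quasi-static potential problem
#'
#' Solves div(sigma grad V) = 0 with Dirichlet values on the active
#' electrode masks and zero-flux conditions on the outer boundary and the
#' insulated shafts. In `field_dependent` mode the conductivity at every
#' node is sigma(|E|) of the converged solution, reached by Picard
#' (fixed-point) iteration with under-relaxation 0.5; `constant_sigma` mode
#' solves the constant-coefficient Laplace problem in a single step.
#'
#' @param grid an [ire_grid][build_grid()].
#' @param props a [tissue_properties()] object.
#' @param voltage applied voltage in V; defaults to the grid's electrode
#'   configuration.
#' @param mode `"field_dependent"` (default) or `"constant_sigma"`.
#' @param tol relative residual tolerance of the nonlinear conservation
#'   equation (default 1e-8).
#' @param max_iter maximum Picard iterations (default 100).
#' @param relax under-relaxation factor for the conductivity update.
#' @return object of class `potential_field`: `V` (nx x ny matrix, volts;
#'   NA on the insulated shafts), `sigma` (node conductivities), applied
#'   voltage, iteration count, final residual and residual history.
#' @export
solve_potential <- function(grid, props, voltage = NULL,
                            mode = c("field_dependent", "constant_sigma"),
                            tol = 1e-8, max_iter = 100, relax = 0.5) {
  stopifnot(inherits(grid, "ire_grid"), inherits(props, "tissue_properties"))
  mode <- match.arg(mode)
  if (is.null(voltage)) voltage <- grid$electrodes$voltage
  if (!is.finite(voltage) || voltage < 0) stop("voltage must be non-negative")

  region <- grid$region
  Vfull <- matrix(NA_real_, grid$nx, grid$ny)
  Vfull[region == REGION_LEFT_ACTIVE] <- voltage
  Vfull[region == REGION_RIGHT_ACTIVE] <- 0
  tis <- region == REGION_TISSUE

  if (voltage == 0) {
    Vfull[tis] <- 0
    pot <- structure(list(V = Vfull, sigma = .node_sigma(grid, props, matrix(0, grid$nx, grid$ny)),
                          applied_voltage = 0, iterations = 0L, residual = 0,
                          residual_history = numeric(0), mode = mode),
                     class = "potential_field")
    return(pot)
  }

  Emag <- matrix(0, grid$nx, grid$ny)
  sig <- .node_sigma(grid, props, Emag)
  niter <- if (mode == "constant_sigma") 1L else max_iter
  hist <- numeric(0)
  res <- NA_real_
  for (it in seq_len(niter)) {
    sys <- .assemble_electric(grid, sig, voltage)
    if (it > 1L) {
      # nonlinear residual with conductivities already consistent with V
      r <- sys$A %*% Vfull[sys$unknown] - sys$b
      res <- sqrt(sum(r^2)) / max(sqrt(sum(sys$b^2)), .Machine$double.eps)
      hist <- c(hist, res)
      if (res < tol) break
    }
    ch <- Matrix::Cholesky(Matrix::forceSymmetric(sys$A), LDL = FALSE)
    Vfull[sys$unknown] <- as.numeric(Matrix::solve(ch, sys$b))
    if (mode == "constant_sigma") {
      r <- sys$A %*% Vfull[sys$unknown] - sys$b
      res <- sqrt(sum(r^2)) / max(sqrt(sum(sys$b^2)), .Machine$double.eps)
      hist <- c(hist, res)
      break
    }
    Emag <- .gradient_magnitude(Vfull, grid)
    sig_new <- .node_sigma(grid, props, Emag)
    sig[tis] <- sig[tis] + relax * (sig_new[tis] - sig[tis])
  }
  if (mode == "field_dependent" && (is.na(res) || res >= tol))
    stop(sprintf("Picard iteration did not converge within %d iterations (residual %.3e); history: %s",
                 max_iter, res, paste(signif(utils::tail(hist, 5), 3), collapse = ", ")))
  structure(list(V = Vfull, sigma = sig, applied_voltage = voltage,
                 iterations = it, residual = res, residual_history = hist,
                 mode = mode),
            class = "potential_field")
}

# internal: |grad V| by central differences (one-sided next to holes and
# boundaries, zero where no finite neighbor exists)
.gradient_magnitude <- function(V, grid) {
  h <- grid$h; nx <- grid$nx; ny <- grid$ny
  pad_na <- function(n) rep(NA_real_, n)
  Vl <- rbind(pad_na(ny), V[-nx, , drop = FALSE])
  Vr <- rbind(V[-1, , drop = FALSE], pad_na(ny))
  Vu <- cbind(pad_na(nx), V[, -ny, drop = FALSE])
  Vd <- cbind(V[, -1, drop = FALSE], pad_na(nx))
  dd <- function(Vm, Vp) {
    g <- (Vp - Vm) / (2 * h)
    fwd <- (Vp - V) / h
    bwd <- (V - Vm) / h
    g[!is.finite(g)] <- fwd[!is.finite(g)]
    g[!is.finite(g)] <- bwd[!is.finite(g)]
    g[!is.finite(g)] <- 0
    g
  }
  Ex <- dd(Vl, Vr)
  Ey <- dd(Vu, Vd)
  sqrt(Ex^2 + Ey^2)
}

#' Electric-field magnitude from a solved potential
#'
#' Central differences in the interior, one-sided next to insulated shafts
#' and boundaries; |E| is zero inside the (equipotential) electrodes.
#'
#' @param potential a [potential_field][solve_potential()].
#' @param grid the grid the potential was solved on.
#' @return object of class `field_magnitude` with matrix `E` (V/m).
#' @export
field_magnitude <- function(potential, grid) {
  stopifnot(inherits(potential, "potential_field"), inherits(grid, "ire_grid"))
  E <- .gradient_magnitude(potential$V, grid)
  E[grid$region == REGION_LEFT_ACTIVE] <- 0
  E[grid$region == REGION_RIGHT_ACTIVE] <- 0
  E[grid$region == REGION_SHAFT] <- 0
  structure(list(E = E, applied_voltage = potential$applied_voltage),
            class = "field_magnitude")
}

#' Write a node field as CSV (x_mm, y_mm, value)
#'
#' @param values nx x ny matrix (e.g. `potential$V` or `field$E`).
#' @param grid the corresponding grid.
#' @param path output CSV path.
#' @export
write_field_csv <- function(values, grid, path) {
  stopifnot(inherits(grid, "ire_grid"))
  d <- data.frame(x_mm = rep(grid$x * 1e3, times = grid$ny),
                  y_mm = rep(grid$y * 1e3, each = grid$nx),
                  value = as.numeric(values))
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
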