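# Quorum-sensing circuit kinetics and the extracellular signal field.
#
# Each bacterial cell synthesizes the diffusible signal (AHL) at a rate with
# a basal term plus a Hill-type positive-feedback term in the locally
# perceived extracellular concentration Q. Downstream of the QS promoter an
# immature GFP pool is translated, matures, and is degraded by a saturable
# protease; the population mean of mature GFP against a detection threshold
# defines "activation". The extracellular field obeys
#   dQ/dt = div(Dsignal grad Q) - Rd Q
# on a regular grid: zero-concentration (Dirichlet) x-boundaries, periodic
# or Dirichlet y-boundaries, explicit 5-point stencil with stability-bounded
# substeps. Cells deposit produced molecules into their containing grid
# cell; the count-to-concentration conversion uses the cell volume
# dx * dy * depth with a slab depth of 1 um (the depth implied by the
# study's own agent-count <-> concentration mapping).

AVOGADRO <- 6.02214076e23

#' AHL production rate of one cell
#'
#' `A_t = eta * (A1 + A2 * Q^H / (Q^H + Q0^H))`: basal synthesis plus
#' Hill-type positive feedback in the perceived signal concentration. By
#' default the RBS strength `eta` scales the whole rate as written; set
#' `eta_scales_basal = FALSE` in [qs_params()] for the alternative reading
#' where only the upregulated term is scaled.
#'
#' @param Q perceived extracellular AHL concentration, nM (vectorized).
#' @param params a [qs_params()].
#' @return production rate, molecules/s.
#' @export
production_rate <- function(Q, params = qs_params()) {
  h <- hill_term(Q, params)
  if (params$eta_scales_basal) {
    params$eta * (params$A1 + params$A2 * h)
  } else {
    params$A1 + params$eta * params$A2 * h
  }
}

hill_term <- function(Q, params) {
  qh <- Q^params$H
  out <- qh / (qh + params$Q0^params$H)
  out[Q <= 0] <- 0
  out
}

#' Advance intracellular GFP kinetics by one Euler step
#'
#' Explicit Euler update of the immature/mature GFP pair:
#' `dGi/dt = ktr * hill(Q) - kGm*Gi - mu*Gi - kdeg * Gi/(Gi+Gm+Km)`,
#' `dGm/dt = kGm*Gi - mu*Gm - kdeg * Gm/(Gi+Gm+Km)`.
#' Growth dilution `mu` is `ln 2 / tau_dbl` (0 with growth off). States are
#' clipped at zero. The fastest rate at the default parameters is
#' ~`kdeg/Km` + `kGm` ~ 3.7e-3 1/s, so any `dt` up to a few seconds is
#' comfortably stable; the orchestrator uses sub-second steps.
#'
#' @param Gi,Gm immature and mature GFP, molecules/cell (vectorized).
#' @param Q perceived AHL, nM.
#' @param dt step, seconds.
#' @param params a [qs_params()].
#' @param mu growth-dilution rate, 1/s.
#' @return list with updated `Gi`, `Gm`.
#' @export
gfp_step <- function(Gi, Gm, Q, dt, params = qs_params(), mu = 0) {
  denom <- Gi + Gm + params$Km
  dGi <- params$ktr * hill_term(Q, params) - params$kGm * Gi - mu * Gi -
    params$kdeg * Gi / denom
  dGm <- params$kGm * Gi - mu * Gm - params$kdeg * Gm / denom
  list(Gi = pmax(0, Gi + dt * dGi), Gm = pmax(0, Gm + dt * dGm))
}

#' Discretized extracellular signal field
#'
#' Regular grid over `[xlim[1], xlim[2]] x [ylim[1], ylim[2]]` with square
#' cells of side `dx` and slab thickness `depth`. Concentrations `Q` are in
#' nM. The x-extremes are zero-concentration (Dirichlet) boundaries; the
#' y-boundary is periodic by default or Dirichlet for closed domains.
#'
#' @param xlim,ylim extents, um.
#' @param dx grid spacing, um (cells are dx-by-dx).
#' @param depth slab thickness, um (default 1; this value is forced by the
#'   agent-count to volumetric-concentration mapping used throughout).
#' @param y_boundary `"periodic"` or `"dirichlet"`.
#' @return object of class `signal_grid`.
#' @export
signal_grid <- function(xlim, ylim, dx = 10, depth = 1,
                        y_boundary = c("periodic", "dirichlet")) {
  y_boundary <- match.arg(y_boundary)
  nx <- round(diff(xlim) / dx)
  ny <- round(diff(ylim) / dx)
  stopifnot(nx >= 3L, ny >= 3L, dx > 0, depth > 0)
  structure(
    list(nx = nx, ny = ny, dx = dx, depth = depth,
         x0 = xlim[1L], y0 = ylim[1L],
         y_boundary = y_boundary,
         Q = matrix(0, nx, ny)),
    class = "signal_grid")
}

#' @export
print.signal_grid <- function(x, ...) {
  cat(sprintf(
    "<signal_grid: %d x %d cells of %g um (depth %g um), y %s, max Q %.3g nM>\n",
    x$nx, x$ny, x$dx, x$depth, x$y_boundary, max(x$Q)))
  invisible(x)
}

# Containing cell of a point; positions exactly on a cell edge belong to
# the lower-index cell. Errors for positions outside the grid.
cell_index <- function(grid, x, y) {
  if (any(x < grid$x0 | x > grid$x0 + grid$nx * grid$dx |
          y < grid$y0 | y > grid$y0 + grid$ny * grid$dx))
    stop("position outside the signal grid")
  ix <- pmax(1L, as.integer(ceiling((x - grid$x0) / grid$dx)))
  iy <- pmax(1L, as.integer(ceiling((y - grid$y0) / grid$dx)))
  list(ix = pmin(ix, grid$nx), iy = pmin(iy, grid$ny))
}

#' Signal concentration perceived at a position
#'
#' Returns the concentration of the grid cell containing the position (the
#' same cell into which an agent at that position deposits).
#'
#' @param grid a [signal_grid()].
#' @param x,y positions, um (vectorized).
#' @return perceived concentrations, nM.
#' @export
perceive <- function(grid, x, y) {
  ci <- cell_index(grid, x, y)
  grid$Q[cbind(ci$ix, ci$iy)]
}

#' Deposit molecules into the field
#'
#' Each source's molecule count is converted to a concentration increment
#' over its containing cell: `dQ[nM] = molecules / (N_A * V_L) * 1e9` with
#' `V_L = dx * dy * depth * 1e-15` litres.
#'
#' @param grid a [signal_grid()].
#' @param x,y source positions, um.
#' @param molecules molecule counts (same length as `x`).
#' @return the grid with updated `Q`.
#' @export
deposit <- function(grid, x, y, molecules) {
  ci <- cell_index(grid, x, y)
  v_litres <- grid$dx * grid$dx * grid$depth * 1e-15
  dq <- molecules / (AVOGADRO * v_litres) * 1e9
  lin <- ci$ix + (ci$iy - 1L) * grid$nx
  acc <- rowsum(dq, lin)
  grid$Q[as.integer(rownames(acc))] <- grid$Q[as.integer(rownames(acc))] + acc
  grid
}

#' Advance the signal field
#'
#' Deposits the sources (if any), then advances diffusion and first-order
#' degradation over `dt` seconds. Diffusion uses the explicit 5-point
#' stencil in substeps bounded by `0.9 * dx^2 / (4 D)`; degradation is
#' applied as the exact factor `exp(-Rd dt)`.
#'
#' @param grid a [signal_grid()].
#' @param dt time to advance, seconds.
#' @param params a [qs_params()] (supplies `Dsignal`, `Rd`).
#' @param sources optional list with `x`, `y`, `molecules` for deposition
#'   before transport.
#' @return the advanced grid.
#' @export
field_step <- function(grid, dt, params = qs_params(), sources = NULL) {
  if (!is.null(sources))
    grid <- deposit(grid, sources$x, sources$y, sources$molecules)
  D <- params$Dsignal
  if (D > 0 && dt > 0) {
    dt_max <- 0.9 * grid$dx^2 / (4 * D)
    n_sub <- max(1L, ceiling(dt / dt_max))
    h <- dt / n_sub
    lam <- D * h / grid$dx^2
    Q <- grid$Q
    nx <- grid$nx
    ny <- grid$ny
    periodic_y <- grid$y_boundary == "periodic"
    zx <- numeric(ny)
    zy <- numeric(nx)
    for (i in seq_len(n_sub)) {
      Qxm <- rbind(zx, Q[-nx, , drop = FALSE], deparse.level = 0)
      Qxp <- rbind(Q[-1L, , drop = FALSE], zx, deparse.level = 0)
      if (periodic_y) {
        Qym <- cbind(Q[, ny], Q[, -ny, drop = FALSE], deparse.level = 0)
        Qyp <- cbind(Q[, -1L, drop = FALSE], Q[, 1L], deparse.level = 0)
      } else {
        Qym <- cbind(zy, Q[, -ny, drop = FALSE], deparse.level = 0)
        Qyp <- cbind(Q[, -1L, drop = FALSE], zy, deparse.level = 0)
      }
      Q <- Q + lam * (Qxm + Qxp + Qym + Qyp - 4 * Q)
    }
    grid$Q <- Q
  }
  if (params$Rd > 0 && dt > 0)
    grid$Q <- grid$Q * exp(-params$Rd * dt)
  grid
}

#' Total signal mass on the grid
#'
#' @param grid a [signal_grid()].
#' @return total molecules represented by the field.
#' @export
total_signal <- function(grid) {
  v_litres <- grid$dx * grid$dx * grid$depth * 1e-15
  sum(grid$Q) * 1e-9 * AVOGADRO * v_litres
}

#' First threshold crossing of the population-mean GFP signal
#'
#' Returns the first time the recorded population mean of mature GFP
#' exceeds the detection threshold, linearly interpolating between samples.
#' If the series never crosses, returns `NA` (the not-activated sentinel).
#'
#' @param times sample times, seconds.
#' @param mean_gm population-mean mature GFP, molecules/bacterium.
#' @param threshold detection threshold (default from [qs_params()]).
#' @return crossing time in seconds, or `NA_real_`.
#' @export
activation_time <- function(times, mean_gm,
                            threshold = qs_params()$gfp_threshold) {
  stopifnot(length(times) == length(mean_gm))
  if (length(times) == 0L) stop("empty history")
  above <- mean_gm > threshold
  if (!any(above)) return(NA_real_)
  i <- which(above)[1L]
  if (i == 1L) return(times[1L])
  t0 <- times[i - 1L]; t1 <- times[i]
  g0 <- mean_gm[i - 1L]; g1 <- mean_gm[i]
  t0 + (threshold - g0) / (g1 - g0) * (t1 - t0)
}
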