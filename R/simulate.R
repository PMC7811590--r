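#' Simulation grid settings
#'
#' Spatial step, time step and cycle control for the Lax--Wendroff solver.
#' The defaults are a fine production grid (0.025 mm, 1.34e-5 s); desk-scale
#' analyses pass coarser values. The time step is rounded so that an integer
#' number of steps spans one cardiac cycle, and the per-vessel spatial step
#' is \code{L / ceiling(L / dx)} so each vessel has at least three nodes.
#'
#' @param dx spatial step, cm.
#' @param dt time step, s.
#' @param n_cycles maximum number of cardiac cycles to run.
#' @param convergence_tol relative cycle-to-cycle maximum pressure change
#'   below which the solution is declared periodic and the run stops.
#' @param n_out number of output samples per cycle (the last cycle is
#'   returned on this grid, plus the closing endpoint).
#' @return an object of class \code{"sim_grid"}.
#' @export
sim_grid <- function(dx = 0.0025, dt = 1.34e-5, n_cycles = 10,
                     convergence_tol = 1e-3, n_out = 128) {
  stopifnot(dx > 0, dt > 0, n_cycles >= 1, convergence_tol > 0, n_out >= 8)
  structure(list(dx = dx, dt = dt, n_cycles = as.integer(n_cycles),
                 convergence_tol = convergence_tol,
                 n_out = as.integer(n_out)),
            class = "sim_grid")
}

#' Simulate pulse-wave propagation on a vessel network
#'
#' Solves the 1D mass/momentum system with the chosen wall law on every
#' vessel, prescribed periodic inflow at the root, flow conservation and
#' pressure continuity at junctions, and three-element Windkessel models at
#' the terminal vessels. Interior nodes advance by the two-step
#' (Richtmyer) Lax--Wendroff scheme; boundary nodes are closed by the
#' outgoing-characteristic equations solved with damped Newton iteration,
#' and the Windkessel ODE is discretized by the trapezoidal rule. The run
#' starts from rest (A = A0, q = 0) and continues until the pressure field
#' is cycle-to-cycle periodic within \code{grid$convergence_tol} or
#' \code{grid$n_cycles} is reached; the last computed cycle is returned.
#'
#' @param network a \code{\link{vessel_network}}.
#' @param wall a \code{\link{wall_model}}.
#' @param windkessel data frame with columns \code{id}, \code{R1},
#'   \code{R2}, \code{C} (cgs), one row per terminal vessel — see
#'   \code{\link{apply_scalings}}.
#' @param inflow data frame with columns \code{time_s}, \code{value}: one
#'   period of root inflow, ml/s.
#' @param grid a \code{\link{sim_grid}}.
#' @param constants \code{\link{physical_constants}}.
#' @return An object of class \code{"haemo_sim"}: per-vessel matrices
#'   \code{A} (cm^2), \code{q} (ml/s) and \code{p} (mmHg) with dimension
#'   nodes x (n_out + 1), the output times \code{t} (s, spanning one cycle
#'   including both endpoints), per-vessel node coordinates \code{x},
#'   convergence information and the maximum Courant number encountered.
#' @examples
#' net <- generate_tree(3, seed = 1)
#' wall <- wall_model("linear", "constant", f3 = 5e4)
#' wk <- apply_scalings(nominal_windkessel(net, 0.16, 14), 1, 1, 1)
#' qin <- synthetic_inflow(inflow_spec(), n = 64)
#' sim <- simulate_network(net, wall, wk, qin,
#'                         sim_grid(dx = 0.05, dt = 1e-4, n_cycles = 5))
#' @export
simulate_network <- function(network, wall, windkessel, inflow,
                             grid = sim_grid(),
                             constants = physical_constants()) {
  v <- network$vessels
  stopifnot(inherits(wall, "wall_model"), inherits(grid, "sim_grid"))
  if (is.list(inflow) && !is.data.frame(inflow)) inflow <- as.data.frame(inflow)
  if (!all(c("time_s", "value") %in% names(inflow)))
    stop("inflow must have columns time_s and value")
  term <- v$id[v$terminal]
  if (!setequal(windkessel$id, term))
    stop("windkessel table must cover exactly the terminal vessels")
  wk <- windkessel[match(term, windkessel$id), , drop = FALSE]

  chi <- network_stiffness(network, wall)
  idx <- function(id) match(id, v$id) - 1L  # 0-based for C++
  junc <- network$junctions
  jm <- if (nrow(junc)) {
    matrix(as.integer(idx(junc)), nrow(junc), 3)
  } else matrix(integer(0), 0, 3)

  res <- .lw_simulate(
    L = v$length_cm, A0 = v$A0_cm2, chi = chi,
    wall_kind = if (wall$kind == "linear") 0L else 1L,
    gamma = if (is.null(wall$gamma)) 1 else wall$gamma,
    junctions = jm, root = idx(network$root),
    terminal_idx = as.integer(idx(wk$id)),
    R1 = wk$R1, R2 = wk$R2, Cap = wk$C,
    inflow_t = inflow$time_s, inflow_q = inflow$value,
    rho = constants$rho, mu = constants$mu,
    delta = boundary_layer_thickness(constants),
    period = constants$period,
    dx = grid$dx, dt = grid$dt, n_cycles = grid$n_cycles,
    conv_tol = grid$convergence_tol, n_out = grid$n_out)

  p <- lapply(res$p_cgs, function(m) m / constants$conv)
  names(res$A) <- names(res$q) <- names(p) <- names(res$x) <- as.character(v$id)
  structure(list(A = res$A, q = res$q, p = p, x = res$x, t = res$t,
                 dt = res$dt, cycles = res$cycles,
                 converged = res$converged, courant_max = res$courant_max,
                 vessel_ids = v$id, network = network, wall = wall,
                 grid = grid, constants = constants),
            class = "haemo_sim")
}

#' @export
print.haemo_sim <- function(x, ...) {
  cat("haemo_sim:", length(x$p), "vessels,", length(x$t), "output times,",
      x$cycles, "cycles run,",
      if (isTRUE(x$converged)) "periodic" else "not yet periodic", "\n")
  cat(sprintf("  max Courant number %.3f; MPA pressure range %.2f-%.2f mmHg\n",
              x$courant_max,
              min(x$p[[as.character(x$network$root)]]),
              max(x$p[[as.character(x$network$root)]])))
  invisible(x)
}

#' Extract a pressure (or flow) time series from a simulation
#'
#' @param sim a \code{\link{simulate_network}} result.
#' @param vessel vessel id.
#' @param frac relative position along the vessel in [0, 1]; 0 is the
#'   proximal (inlet) end. The nearest grid node is used. Default is the
#'   midpoint, where a catheter tip would sit.
#' @param times optional times (s, within one period) to interpolate to;
#'   default returns the solver's own output grid.
#' @param what \code{"p"} (mmHg), \code{"q"} (ml/s) or \code{"A"} (cm^2).
#' @return data frame with columns \code{time_s} and \code{value}.
#' @export
sim_series <- function(sim, vessel, frac = 0.5, times = NULL, what = "p") {
  key <- as.character(vessel)
  if (!key %in% names(sim$p)) stop("unknown vessel id: ", vessel)
  m <- sim[[what]][[key]]
  node <- 1 + round(frac * (nrow(m) - 1))
  series <- m[node, ]
  if (is.null(times)) return(data.frame(time_s = sim$t, value = series))
  data.frame(time_s = times,
             value = stats::approx(sim$t, series, xout = times,
                                   rule = 2)$y)
}

#' Cycle-averaged pressure per vessel
#'
#' Trapezoidal time average of the pressure at each vessel's midpoint over
#' the returned cycle.
#'
#' @inheritParams sim_series
#' @return named numeric vector (mmHg), names are vessel ids.
#' @export
cycle_average_pressure <- function(sim, frac = 0.5) {
  tt <- sim$t
  w <- diff(tt)
  vapply(names(sim$p), function(key) {
    m <- sim$p[[key]]
    node <- 1 + round(frac * (nrow(m) - 1))
    y <- m[node, ]
    sum(0.5 * (y[-1] + y[-length(y)]) * w) / (tt[length(tt)] - tt[1])
  }, numeric(1))
}

#' Check the CFL condition on a computed solution
#'
#' Recomputes the Courant number \eqn{\Delta t\,(|\bar u| + c)/\Delta x}
#' over all stored nodes and output times, with the local wave speed from
#' the wall law.
#'
#' @param sim a \code{\link{simulate_network}} result.
#' @return list with \code{ok} (logical) and \code{courant} (max Courant
#'   number over the stored fields).
#' @export
check_cfl <- function(sim) {
  v <- sim$network$vessels
  chi <- network_stiffness(sim$network, sim$wall)
  cmax <- 0
  for (k in seq_along(sim$A)) {
    A <- sim$A[[k]]
    u <- abs(sim$q[[k]] / A)
    cc <- wave_speed(A, v$A0_cm2[k], sim$wall$kind, chi[k],
                     if (is.null(sim$wall$gamma)) 1 else sim$wall$gamma,
                     sim$constants$rho)
    dxv <- sim$x[[k]][2] - sim$x[[k]][1]
    cmax <- max(cmax, max((u + cc) * sim$dt / dxv))
  }
  list(ok = cmax <= 1, courant = cmax)
}

#' Mass balance over the returned cycle
#'
#' Integrates the inflow at the root inlet, the outflow through every
#' terminal outlet and the change of stored volume
#' \eqn{\sum_v \int A\,dx} between the first and last output samples.
#' For a periodic solution inflow equals outflow plus storage to solver
#' accuracy.
#'
#' @param sim a \code{\link{simulate_network}} result.
#' @return list with \code{inflow_ml}, \code{outflow_ml},
#'   \code{storage_ml} and \code{relative_error} =
#'   |inflow - outflow - storage| / inflow.
#' @export
mass_balance <- function(sim) {
  tt <- sim$t
  trapz <- function(y) sum(0.5 * (y[-1] + y[-length(y)]) * diff(tt))
  root_key <- as.character(sim$network$root)
  q_in <- trapz(sim$q[[root_key]][1, ])
  v <- sim$network$vessels
  q_out <- 0
  for (id in v$id[v$terminal]) {
    m <- sim$q[[as.character(id)]]
    q_out <- q_out + trapz(m[nrow(m), ])
  }
  storage <- 0
  for (key in names(sim$A)) {
    A <- sim$A[[key]]
    x <- sim$x[[key]]
    dxv <- x[2] - x[1]
    vol <- function(col) sum(0.5 * (col[-1] + col[-length(col)]) * dxv)
    storage <- storage + vol(A[, ncol(A)]) - vol(A[, 1])
  }
  list(inflow_ml = q_in, outflow_ml = q_out, storage_ml = storage,
       relative_error = abs(q_in - q_out - storage) / abs(q_in))
}
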