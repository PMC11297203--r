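#' Parameters of the occupancy approximation
#'
#' When the patch graph is complete, the meta-population reduces to a
#' Levins-type occupancy model driven by the two collective-level life-history
#' constants: collectives die at rate `1/tau` and emit propagules at the
#' lifetime-normalised rate `rho/tau`; a propagule targets a uniformly random
#' patch and succeeds only when that patch is empty.
#'
#' @param rho expected lifetime propagule output of a collective.
#' @param tau expected collective lifespan (must be positive).
#' @param D number of patches (positive integer).
#' @return An object of class `ode_params`.
#' @export
ode_params <- function(rho, tau, D) {
  stopifnot(rho >= 0, tau > 0, D >= 1, D == floor(D))
  structure(list(rho = rho, tau = tau, D = as.integer(D)),
            class = "ode_params")
}

#' Right-hand side of the occupancy ODE
#'
#' \deqn{\frac{do}{dt} = \frac{\rho}{\tau}\,o\,\frac{D-o}{D} - \frac{o}{\tau}}
#'
#' Extinction (`o = 0`) is absorbing; at full occupancy (`o = D`) every
#' propagule is dead on arrival and the derivative is negative.
#'
#' @param occupied number of occupied patches, in `[0, D]`.
#' @param params an [ode_params()].
#' @return the time derivative of `occupied` (a single number).
#' @export
ode_rhs <- function(occupied, params) {
  stopifnot(inherits(params, "ode_params"))
  with(params, (rho / tau) * occupied * (D - occupied) / D - occupied / tau)
}

#' Integrate the occupancy ODE
#'
#' Thin wrapper around [deSolve::ode()] for the single-compartment occupancy
#' system.
#'
#' @param o0 initial number of occupied patches.
#' @param params an [ode_params()].
#' @param times output time points.
#' @return A data frame with columns `time` and `occupied`.
#' @export
integrate_occupancy <- function(o0, params, times = seq(0, 500, by = 1)) {
  rhs <- function(t, y, p) list(ode_rhs(y, p))
  out <- deSolve::ode(y = c(occupied = o0), times = times, func = rhs,
                      parms = params)
  data.frame(time = out[, "time"], occupied = out[, "occupied"])
}

#' Stable equilibrium occupancy
#'
#' The occupancy ODE has the logistic-type stable fixed point
#' `o* = D (1 - 1/rho)` when `rho > 1` and only the extinction equilibrium
#' `o* = 0` when `rho <= 1`: a meta-population persists precisely when each
#' collective more than replaces itself over its lifetime. Note `tau` scales
#' time but not the equilibrium.
#'
#' @param params an [ode_params()].
#' @return the stable equilibrium number of occupied patches.
#' @export
equilibrium_occupancy <- function(params) {
  stopifnot(inherits(params, "ode_params"))
  if (params$rho <= 1) 0 else params$D * (1 - 1 / params$rho)
}

#' Viability of a trait value
#'
#' A trait is viable when the meta-population persists, i.e. when the
#' expected lifetime propagule output exceeds one.
#'
#' @inheritParams collective_life_history
#' @return `TRUE` iff `rho(theta) > 1`.
#' @export
viability <- function(model, theta, R) {
  rho_of(as_trait_model(model), theta, R) > 1
}

#' Upper viability threshold of the trait
#'
#' Solves `rho(theta) = 1` on the dispersal-starved side of the landscape:
#' the root is bracketed between the global maximiser of `rho` and 1 and
#' found by [stats::uniroot()] bisection. For the intrinsic model this is the
#' threshold `theta_max < 1` above which collectives burn resources on
#' duplication faster than they export propagules.
#'
#' @inheritParams collective_life_history
#' @param tol root tolerance on `theta` (default `1e-6`).
#' @return the root `theta_max`, or `1` when `rho > 1` all the way to the
#'   boundary (no root in the bracket).
#' @export
solve_theta_max <- function(model, R, tol = 1e-6) {
  model <- as_trait_model(model)
  if (R < 2) stop("`R` must be >= 2", call. = FALSE)
  grid <- seq(0.01, 0.999, by = 0.001)
  rho <- life_history_grid(model, grid, R)$rho
  peak <- grid[which.max(rho)]
  f <- function(th) rho_of(model, th, R) - 1
  if (f(1 - 1e-9) > 0) return(1)
  stats::uniroot(f, c(peak, 1 - 1e-9), tol = tol)$root
}
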