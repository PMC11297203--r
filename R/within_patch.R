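#' Exact collective-level life history by dynamic programming
#'
#' A collective is founded by a single particle in a fresh patch
#' (`n = 1`, `r = R`). Events occur at total rate `n` (each particle consumes
#' resources at rate 1); at each event a uniformly chosen particle consumes
#' one resource item and duplicates with probability `p(theta, n)` or
#' disperses as a propagule otherwise. The collective dies when resources are
#' exhausted (all residents die) or when the patch is vacated by dispersal.
#'
#' Two collective-level quantities summarise the whole within-patch process:
#' `rho`, the expected lifetime number of propagules, and `tau`, the expected
#' collective lifespan (in units of the particle consumption rate). Both are
#' computed exactly by first-step analysis over the finite state space
#' `(n, r)`:
#' \deqn{E(n, r) = p\,E(n{+}1, r{-}1) + (1-p)\,(1 + E(n{-}1, r{-}1))}
#' \deqn{T(n, r) = 1/n + p\,T(n{+}1, r{-}1) + (1-p)\,T(n{-}1, r{-}1)}
#' with boundaries `E = T = 0` at `r = 0` and `n = 0`, and
#' `p = p(theta, n)`. Since every duplication consumes one resource,
#' `n <= R + 1` always.
#'
#' The perfect-coordination ceiling is `rho = R/2`: at most one propagule per
#' two resource items (one spent duplicating the future emigrant, one spent
#' on its departure).
#'
#' @param model a [trait_model()] or its kind as a string.
#' @param theta trait value in `[0, 1]`.
#' @param R patch resource endowment, a positive integer.
#' @return An object of class `life_history`: a list with fields `rho`,
#'   `tau`, `model`, `theta`, `R`.
#' @examples
#' collective_life_history("intrinsic", theta = 0, R = 50)        # rho = tau = 1
#' collective_life_history("density_dependent", theta = 1, R = 20) # rho = R/2
#' @export
collective_life_history <- function(model, theta, R) {
  model <- as_trait_model(model)
  check_theta(theta)
  if (length(theta) != 1L) stop("`theta` must be a single value", call. = FALSE)
  lh <- life_history_tables(model, theta, R)
  structure(list(rho = lh$rho, tau = lh$tau,
                 model = model$kind, theta = theta, R = as.integer(R)),
            class = "life_history")
}

#' @export
print.life_history <- function(x, ...) {
  cat(sprintf("<life_history> %s model, theta = %g, R = %d\n",
              x$model, x$theta, x$R))
  cat(sprintf("  rho (expected propagules): %.6g\n", x$rho))
  cat(sprintf("  tau (expected lifespan):   %.6g\n", x$tau))
  invisible(x)
}

# Backward recursion over r = 0..R, vectorised over n = 0..R+1.
life_history_tables <- function(model, theta, R) {
  if (!is.numeric(R) || length(R) != 1L || R < 1 || R != floor(R)) {
    stop("`R` must be a positive integer >= 1", call. = FALSE)
  }
  nmax <- R + 1L
  n <- seq_len(nmax)
  p <- duplication_probability(model, theta, n)
  Ep <- numeric(nmax + 1L)  # index i holds state n = i - 1; r = 0 layer
  Tt <- numeric(nmax + 1L)
  for (r in seq_len(R)) {
    E_up <- c(Ep[-(1:2)], 0)   # E(n + 1, r - 1), n = 1..nmax (n = nmax + 1 unreachable)
    E_dn <- Ep[seq_len(nmax)]  # E(n - 1, r - 1)
    T_up <- c(Tt[-(1:2)], 0)
    T_dn <- Tt[seq_len(nmax)]
    Ep <- c(0, p * E_up + (1 - p) * (1 + E_dn))
    Tt <- c(0, 1 / n + p * T_up + (1 - p) * T_dn)
  }
  list(rho = Ep[2L], tau = Tt[2L])
}

# Same recursion with theta varying across columns: one (R x theta-grid)
# sweep instead of length(thetas) scalar sweeps.
life_history_grid <- function(model, thetas, R) {
  model <- as_trait_model(model)
  check_theta(thetas)
  nmax <- R + 1L
  n <- seq_len(nmax)
  k <- length(thetas)
  p <- switch(model$kind,
    intrinsic = matrix(thetas, nmax, k, byrow = TRUE),
    density_dependent = rbind(thetas,
                              matrix(1 - thetas, nmax - 1L, k, byrow = TRUE))
  )
  Ep <- matrix(0, nmax + 1L, k)
  Tt <- matrix(0, nmax + 1L, k)
  zero <- matrix(0, 1L, k)
  for (r in seq_len(R)) {
    E_up <- rbind(Ep[-(1:2), , drop = FALSE], zero)
    E_dn <- Ep[seq_len(nmax), , drop = FALSE]
    T_up <- rbind(Tt[-(1:2), , drop = FALSE], zero)
    T_dn <- Tt[seq_len(nmax), , drop = FALSE]
    Ep <- rbind(zero, p * E_up + (1 - p) * (1 + E_dn))
    Tt <- rbind(zero, (1 / n) + p * T_up + (1 - p) * T_dn)
  }
  list(rho = Ep[2L, ], tau = Tt[2L, ])
}

rho_of <- function(model, theta, R) life_history_tables(as_trait_model(model), theta, R)$rho

#' Life-history curves over a trait grid
#'
#' Evaluates the exact dynamic program on a grid of trait values and returns
#' a tidy table suitable for plotting or for [write_life_history_csv()].
#'
#' @inheritParams collective_life_history
#' @param thetas numeric vector of trait values in `[0, 1]`.
#' @return A data frame with columns `model`, `R`, `theta`, `rho`, `tau`.
#' @export
life_history_curve <- function(model, R, thetas = seq(0, 1, by = 0.01)) {
  model <- as_trait_model(model)
  lh <- life_history_grid(model, thetas, R)
  data.frame(model = model$kind, R = as.integer(R), theta = thetas,
             rho = lh$rho, tau = lh$tau)
}

#' Write life-history curves to CSV
#'
#' @param curves a data frame from [life_history_curve()] (or several row-bound
#'   together).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_life_history_csv <- function(curves, path) {
  utils::write.csv(curves, path, row.names = FALSE)
  invisible(path)
}

#' Monte-Carlo simulation of a single collective
#'
#' One stochastic realisation of the within-patch chain from the founding
#' state (`n = 1`, `r = R`) to absorption. This is an independent check on
#' the dynamic program of [collective_life_history()]: averaging
#' `propagules` (resp. `lifespan`) over many seeds converges to `rho`
#' (resp. `tau`).
#'
#' @inheritParams collective_life_history
#' @param seed optional integer seed (set before simulating, so identical
#'   seeds give identical trajectories).
#' @return A list with `propagules` (integer), `lifespan` (numeric) and
#'   `trajectory`, a data frame with one row per event
#'   (`time`, `n`, `r` after the event).
#' @export
simulate_single_patch <- function(model, theta, R, seed = NULL) {
  model <- as_trait_model(model)
  check_theta(theta)
  if (R < 1 || R != floor(R)) stop("`R` must be a positive integer", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- 1L
  r <- as.integer(R)
  t <- 0
  propagules <- 0L
  times <- numeric(2L * R); ns <- integer(2L * R); rs <- integer(2L * R)
  k <- 0L
  while (n > 0L && r > 0L) {
    t <- t + stats::rexp(1L, rate = n)
    p <- duplication_probability(model, theta, n)
    r <- r - 1L
    if (stats::runif(1L) < p) {
      n <- n + 1L
    } else {
      n <- n - 1L
      propagules <- propagules + 1L
    }
    if (r == 0L) n <- 0L  # depletion kills all residents
    k <- k + 1L
    times[k] <- t; ns[k] <- n; rs[k] <- r
  }
  list(propagules = propagules, lifespan = t,
       trajectory = data.frame(time = times[seq_len(k)], n = ns[seq_len(k)],
                               r = rs[seq_len(k)]))
}

#' Propagule-output landscape and its interior extrema
#'
#' Evaluates `rho(theta)` on a grid, locates interior local maxima and minima
#' by sign changes of the finite differences, and refines each one on the
#' continuous-trait dynamic program by golden-section search
#' ([stats::optimize()]) to the requested tolerance. Boundary points are
#' never reported as interior extrema. Extrema can optionally be restricted
#' to the viable range (`rho > 1`), which is the relevant region for the
#' evolutionary analysis: a landscape feature in a region where collectives
#' cannot replace themselves is ecologically unreachable.
#'
#' @inheritParams collective_life_history
#' @param theta_grid strictly increasing grid in `[0, 1]` with at least three
#'   points.
#' @param tol refinement tolerance on `theta` (default `1e-3`).
#' @param viable_only keep only extrema with `rho > 1` (default `TRUE`).
#' @return An object of class `rho_curve`: list with `curve` (data frame
#'   `theta`, `rho`) and `extrema` (data frame `theta`, `rho`, `type` in
#'   `c("max", "min")`, refined positions).
#' @export
rho_curve <- function(model, R, theta_grid = seq(0.001, 0.999, by = 0.001),
                      tol = 1e-3, viable_only = TRUE) {
  if (length(theta_grid) < 3L) {
    stop("`theta_grid` must contain at least 3 points", call. = FALSE)
  }
  if (any(diff(theta_grid) <= 0)) {
    stop("`theta_grid` must be strictly increasing", call. = FALSE)
  }
  model <- as_trait_model(model)
  rho <- life_history_grid(model, theta_grid, R)$rho
  d <- diff(rho)
  s <- sign(d)
  # index i (2..k-1) is an interior extremum when the difference sign flips
  flips <- which(s[-1] * s[-length(s)] < 0) + 1L
  ext <- lapply(flips, function(i) {
    type <- if (rho[i] > rho[i - 1L]) "max" else "min"
    lo <- theta_grid[i - 1L]; hi <- theta_grid[i + 1L]
    f <- function(th) rho_of(model, th, R)
    opt <- stats::optimize(f, c(lo, hi), maximum = (type == "max"), tol = tol)
    theta_hat <- if (type == "max") opt$maximum else opt$minimum
    data.frame(theta = theta_hat, rho = opt$objective, type = type)
  })
  extrema <- if (length(ext)) do.call(rbind, ext) else
    data.frame(theta = numeric(0), rho = numeric(0), type = character(0))
  if (viable_only && nrow(extrema)) extrema <- extrema[extrema$rho > 1, , drop = FALSE]
  rownames(extrema) <- NULL
  structure(list(curve = data.frame(theta = theta_grid, rho = rho),
                 extrema = extrema, model = model$kind, R = as.integer(R)),
            class = "rho_curve")
}

#' @export
print.rho_curve <- function(x, ...) {
  cat(sprintf("<rho_curve> %s model, R = %d, %d grid points\n",
              x$model, x$R, nrow(x$curve)))
  if (nrow(x$extrema)) {
    cat("  interior extrema:\n")
    print(x$extrema, row.names = FALSE)
  } else cat("  no interior extrema in the viable range\n")
  invisible(x)
}
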