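#' Invasion fitness of a rare mutant
#'
#' With the resident trait at its ecological equilibrium, the fraction of
#' empty patches is `e* = 1/rho(theta_res)` (from the occupancy model). A
#' rare mutant collective emits `rho(theta_mut)` propagules over its lifetime
#' `tau(theta_mut)`, each succeeding with probability `e*`, and dies at rate
#' `1/tau(theta_mut)`; its per-capita growth rate is
#' \deqn{s(\theta_m, \theta_r) =
#'   \frac{\rho(\theta_m)/\rho(\theta_r) - 1}{\tau(\theta_m)}.}
#' The sign of `s` is the sign of `rho(theta_mut) - rho(theta_res)`:
#' invasion analysis reduces to the propagule-output landscape, and the
#' collective lifespan only rescales the rate of spread.
#'
#' @param theta_mut mutant trait value.
#' @param theta_res resident trait value; the resident must be viable
#'   (`rho > 1`), otherwise there is no resident equilibrium to invade.
#' @inheritParams collective_life_history
#' @return the mutant growth rate (zero when `theta_mut == theta_res`).
#' @export
invasion_fitness <- function(theta_mut, theta_res, model, R) {
  model <- as_trait_model(model)
  check_theta(c(theta_mut, theta_res))
  res <- life_history_tables(model, theta_res, R)
  if (res$rho <= 1) {
    stop("resident is not viable (rho <= 1): no resident equilibrium",
         call. = FALSE)
  }
  mut <- life_history_tables(model, theta_mut, R)
  (mut$rho / res$rho - 1) / mut$tau
}

#' Pairwise invasibility plot (PIP)
#'
#' Sign of the invasion fitness over a (resident, mutant) grid restricted to
#' viable residents.
#'
#' @inheritParams collective_life_history
#' @param grid trait grid for both axes.
#' @return An object of class `pip`: list with `grid`, `sign` (matrix, rows =
#'   mutants, columns = residents; `NA` for non-viable residents) and the
#'   model/R used. Use [as.data.frame()] for a long-format table.
#' @export
pairwise_invasibility <- function(model, R, grid = seq(0.02, 0.98, by = 0.02)) {
  model <- as_trait_model(model)
  lh <- life_history_grid(model, grid, R)
  viable <- lh$rho > 1
  sgn <- matrix(NA_integer_, length(grid), length(grid),
                dimnames = list(mutant = NULL, resident = NULL))
  for (j in which(viable)) {
    sgn[, j] <- sign(lh$rho - lh$rho[j])
  }
  structure(list(grid = grid, sign = sgn, model = model$kind,
                 R = as.integer(R)),
            class = "pip")
}

#' @export
as.data.frame.pip <- function(x, ...) {
  data.frame(theta_res = rep(x$grid, each = length(x$grid)),
             theta_mut = rep(x$grid, times = length(x$grid)),
             sign = as.vector(x$sign))
}

#' @export
print.pip <- function(x, ...) {
  cat(sprintf("<pip> %s model, R = %d, %d x %d grid\n",
              x$model, x$R, length(x$grid), length(x$grid)))
  invisible(x)
}

#' Locate and classify evolutionarily stable strategies
#'
#' Because the sign of invasion fitness equals the sign of
#' `rho(mutant) - rho(resident)`, singular strategies are the stationary
#' points of the propagule-output landscape restricted to the viable range:
#' interior local maxima of `rho` are convergence-stable ESSs, interior local
#' minima are fitness-valley bottoms (evolutionary repellors), and the
#' boundary `theta = 1` is an ESS whenever `rho` is increasing into it and
#' viable there. Interior candidates are detected on a fine grid and refined
#' by golden-section search on the exact dynamic program.
#'
#' @inheritParams collective_life_history
#' @param grid_step trait grid resolution for candidate detection
#'   (default `1e-3`).
#' @param tol refinement tolerance on `theta` (default `1e-3`).
#' @return An object of class `ess_report`: list with `ess` (data frame
#'   `theta`, `rho`, `convergence_stable`, `evolutionarily_stable`,
#'   `boundary`) and `valleys` (data frame `theta`, `rho`).
#' @export
find_ess <- function(model, R, grid_step = 1e-3, tol = 1e-3) {
  model <- as_trait_model(model)
  if (R < 2) stop("`R` must be >= 2", call. = FALSE)
  grid <- seq(grid_step, 1 - grid_step, by = grid_step)
  rc <- rho_curve(model, R, grid, tol = tol, viable_only = TRUE)
  ex <- rc$extrema
  ess <- ex[ex$type == "max", c("theta", "rho"), drop = FALSE]
  if (nrow(ess)) {
    ess$convergence_stable <- TRUE    # attracting: rho increases toward it
    ess$evolutionarily_stable <- TRUE # strict local max: no mutant invades
    ess$boundary <- FALSE
  } else {
    ess <- data.frame(theta = numeric(0), rho = numeric(0),
                      convergence_stable = logical(0),
                      evolutionarily_stable = logical(0),
                      boundary = logical(0))
  }
  valleys <- ex[ex$type == "min", c("theta", "rho"), drop = FALSE]
  # boundary theta = 1: ESS when rho is increasing into the boundary and
  # the boundary value is viable
  rho1 <- rho_of(model, 1, R)
  rho1m <- rho_of(model, 1 - grid_step, R)
  if (rho1 > 1 && rho1 > rho1m) {
    ess <- rbind(ess, data.frame(theta = 1, rho = rho1,
                                 convergence_stable = TRUE,
                                 evolutionarily_stable = TRUE,
                                 boundary = TRUE))
  }
  rownames(ess) <- rownames(valleys) <- NULL
  structure(list(ess = ess, valleys = valleys, model = model$kind,
                 R = as.integer(R)),
            class = "ess_report")
}

#' @export
print.ess_report <- function(x, ...) {
  cat(sprintf("<ess_report> %s model, R = %d\n", x$model, x$R))
  if (nrow(x$ess)) {
    cat("  ESS:\n"); print(x$ess, row.names = FALSE)
  } else cat("  no viable ESS\n")
  if (nrow(x$valleys)) {
    cat("  fitness valleys:\n"); print(x$valleys, row.names = FALSE)
  }
  invisible(x)
}

#' Fold-bifurcation scan over patch size
#'
#' For each integer patch endowment `R` in the range, counts the interior
#' extrema of the viable propagule-output landscape. The fold is the largest
#' `R` at which the interior maximum/minimum pair is absent: for the
#' density-dependent model the fitness valley separating the
#' slightly-anti-coordinated ESS from perfect coordination exists only in
#' patches richer than this threshold.
#'
#' @inheritParams collective_life_history
#' @param R_min,R_max inclusive integer range to scan.
#' @param grid_step trait grid resolution (default `2e-3`).
#' @return An object of class `bifurcation_scan`: list with `scan` (data
#'   frame `R`, `n_interior_extrema`) and `R_star` (largest `R` with no
#'   interior pair; `NA` when the pair exists throughout or never appears).
#' @export
fold_bifurcation_scan <- function(model, R_min, R_max, grid_step = 2e-3) {
  model <- as_trait_model(model)
  stopifnot(R_min >= 2, R_max >= R_min)
  Rs <- seq.int(R_min, R_max)
  grid <- seq(grid_step, 1 - grid_step, by = grid_step)
  counts <- vapply(Rs, function(R) {
    rho <- life_history_grid(model, grid, R)$rho
    viable <- rho > 1
    d <- diff(rho)
    s <- sign(d)
    flips <- which(s[-1] * s[-length(s)] < 0) + 1L
    sum(viable[flips])
  }, integer(1))
  has_pair <- counts >= 2L
  R_star <- if (any(has_pair) && any(!has_pair)) max(Rs[!has_pair]) else NA_integer_
  structure(list(scan = data.frame(R = Rs, n_interior_extrema = counts),
                 R_star = R_star, model = model$kind),
            class = "bifurcation_scan")
}

#' @export
print.bifurcation_scan <- function(x, ...) {
  cat(sprintf("<bifurcation_scan> %s model, R in [%d, %d]\n",
              x$model, min(x$scan$R), max(x$scan$R)))
  cat("  R_star (largest R without the interior max/min pair):",
      x$R_star, "\n")
  invisible(x)
}

#' Deterministic trait-substitution trajectory
#'
#' Mutation-limited evolution: the resident trait takes small steps
#' (`delta_theta` per substitution) in the direction of the local invasion
#' fitness gradient, which under this model is the direction of increasing
#' `rho`. Each environment segment prescribes a patch endowment `R` and a
#' number of substitution steps (`Inf` means run to convergence); within a
#' segment the walk stops early at an attractor (gradient below `grad_tol`)
#' or at a boundary with outward gradient.
#'
#' @inheritParams collective_life_history
#' @param schedule data frame with columns `duration` (number of substitution
#'   steps, may be `Inf`) and `R` (patch endowment for the segment).
#' @param theta0 starting trait value, viable in the first environment.
#' @param delta_theta substitution step size (default `1e-3`).
#' @param grad_tol convergence threshold on the `rho` gradient
#'   (default `1e-8`).
#' @return An object of class `trait_trajectory`: data frame `segment`, `R`,
#'   `step`, `theta` (one row per recorded point) with the final trait in
#'   `attr(, "theta_end")`.
#' @export
trait_substitution_trajectory <- function(model, schedule, theta0,
                                          delta_theta = 1e-3,
                                          grad_tol = 1e-8) {
  model <- as_trait_model(model)
  check_theta(theta0)
  stopifnot(is.data.frame(schedule), all(c("duration", "R") %in% names(schedule)))
  if (!viability(model, theta0, schedule$R[1])) {
    stop("`theta0` is not viable in the first environment", call. = FALSE)
  }
  theta <- theta0
  rows <- list()
  for (seg in seq_len(nrow(schedule))) {
    R <- schedule$R[seg]
    n_steps <- schedule$duration[seg]
    max_steps <- if (is.finite(n_steps)) n_steps else ceiling(2 / delta_theta)
    path <- theta
    step <- 0L
    prev2 <- NA_real_
    while (step < max_steps) {
      g <- rho_gradient(model, theta, R, delta_theta)
      if (abs(g) < grad_tol) break
      theta_new <- theta + sign(g) * delta_theta
      theta_new <- min(max(theta_new, 0), 1)
      if (theta_new == theta) break                    # pinned at a boundary
      if (isTRUE(theta_new == prev2)) break            # oscillating around a peak
      prev2 <- theta
      theta <- theta_new
      step <- step + 1L
      path <- c(path, theta)
    }
    rows[[seg]] <- data.frame(segment = seg, R = R,
                              step = seq_along(path) - 1L, theta = path)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("trait_trajectory", "data.frame")
  attr(out, "theta_end") <- theta
  out
}

# central-difference gradient of rho, one-sided at the trait boundaries
rho_gradient <- function(model, theta, R, h = 1e-3) {
  lo <- max(theta - h, 0)
  hi <- min(theta + h, 1)
  (rho_of(model, hi, R) - rho_of(model, lo, R)) / (hi - lo)
}

#' Endpoint of a trajectory
#' @param x a `trait_trajectory`.
#' @return the final trait value.
#' @export
trajectory_endpoint <- function(x) attr(x, "theta_end")

#' Three formal conditions for trait endogenisation
#'
#' A scaffolded trait value is endogenised — it persists after the
#' environment reverts — precisely when:
#' 1. the non-scaffolding environment carries two alternative evolutionarily
#'    stable trait values (a bistable landscape with a fitness valley);
#' 2. the ancestral-side ESS is absent (evolutionarily unstable) in the
#'    scaffolding environment, so scaffolding generates directional
#'    selection away from it; and
#' 3. the attractor reached under scaffolding lies beyond the
#'    non-scaffolding valley, i.e. inside the basin of attraction of the
#'    derived ESS.
#'
#' @inheritParams collective_life_history
#' @param R_scaffold patch endowment of the scaffolding environment.
#' @param R_nonscaffold patch endowment of the non-scaffolding (ancestral)
#'   environment.
#' @param theta0 ancestral trait value (default 0.5).
#' @return An object of class `endogenisation_report`: list with logical
#'   `condition1`, `condition2`, `condition3`, `endogenisable` (their
#'   conjunction), `basin_boundary_nonscaffold` (valley position, `NA` if
#'   none) and `endpoint_scaffold` (attractor reached under scaffolding from
#'   `theta0`).
#' @export
check_endogenisation_conditions <- function(model, R_scaffold, R_nonscaffold,
                                            theta0 = 0.5) {
  model <- as_trait_model(model)
  stopifnot(R_scaffold >= 2, R_nonscaffold >= 2)
  ns <- find_ess(model, R_nonscaffold)
  sc <- find_ess(model, R_scaffold)

  cond1 <- nrow(ns$ess) >= 2 && nrow(ns$valleys) >= 1
  valley <- if (nrow(ns$valleys)) ns$valleys$theta[1] else NA_real_

  # ancestral-side ESS: nearest non-scaffold ESS below the valley (or to
  # theta0 when the landscape is monostable)
  anc <- if (cond1) {
    below <- ns$ess$theta[ns$ess$theta < valley]
    if (length(below)) max(below) else NA_real_
  } else if (nrow(ns$ess)) {
    ns$ess$theta[which.min(abs(ns$ess$theta - theta0))]
  } else NA_real_

  # condition 2: no scaffold-environment ESS close to the ancestral one
  cond2 <- if (is.na(anc)) FALSE else
    !any(abs(sc$ess$theta - anc) < 0.05)

  # scaffold-environment attractor reached from theta0
  end_sc <- if (nrow(sc$ess)) {
    traj <- trait_substitution_trajectory(
      model, data.frame(duration = Inf, R = R_scaffold), theta0)
    trajectory_endpoint(traj)
  } else NA_real_

  cond3 <- !is.na(end_sc) && !is.na(valley) && end_sc > valley

  structure(list(condition1 = cond1, condition2 = cond2, condition3 = cond3,
                 endogenisable = isTRUE(cond1 && cond2 && cond3),
                 basin_boundary_nonscaffold = valley,
                 endpoint_scaffold = end_sc,
                 model = model$kind, R_scaffold = R_scaffold,
                 R_nonscaffold = R_nonscaffold, theta0 = theta0),
            class = "endogenisation_report")
}

#' @export
print.endogenisation_report <- function(x, ...) {
  cat(sprintf("<endogenisation_report> %s model, scaffold R = %d, ancestral R = %d\n",
              x$model, x$R_scaffold, x$R_nonscaffold))
  cat(sprintf("  1. bistable ancestral landscape:        %s\n", x$condition1))
  cat(sprintf("  2. ancestral ESS lost under scaffold:   %s\n", x$condition2))
  cat(sprintf("  3. scaffold attractor beyond the valley: %s\n", x$condition3))
  cat(sprintf("  => endogenisable: %s\n", x$endogenisable))
  if (!is.na(x$basin_boundary_nonscaffold)) {
    cat(sprintf("  valley at theta = %.3f; scaffold attractor at theta = %.3f\n",
                x$basin_boundary_nonscaffold, x$endpoint_scaffold))
  }
  invisible(x)
}

#' Write a PIP to CSV (long format)
#' @param pip a [pairwise_invasibility()] result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pip_csv <- function(pip, path) {
  utils::write.csv(as.data.frame(pip), path, row.names = FALSE)
  invisible(path)
}
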