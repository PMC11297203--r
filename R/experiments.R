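#' Classify an evolutionary endpoint
#'
#' A population's mean trait is on the coordinated branch when it has crossed
#' the fitness valley of the landscape at the given patch size; the threshold
#' is the valley position computed from the landscape itself (never
#' hard-coded). In a monostable landscape the endpoint is classified by
#' proximity to the single ESS: coordinated when that ESS is the
#' perfect-coordination boundary.
#'
#' @param mean_theta population mean trait value.
#' @inheritParams collective_life_history
#' @param ess optional precomputed [find_ess()] report (avoids recomputation
#'   in replicate loops).
#' @return `"coordinated_branch"` or `"ancestral_branch"`.
#' @export
classify_endpoint <- function(mean_theta, model, R, ess = NULL) {
  if (is.null(ess)) ess <- find_ess(model, R)
  if (nrow(ess$valleys)) {
    if (mean_theta > ess$valleys$theta[1]) "coordinated_branch" else "ancestral_branch"
  } else {
    if (!nrow(ess$ess)) return(NA_character_)
    nearest <- ess$ess$theta[which.min(abs(ess$ess$theta - mean_theta))]
    if (nearest >= 0.99) "coordinated_branch" else "ancestral_branch"
  }
}

#' Temporary-scaffolding experiment
#'
#' Each replicate evolves an ancestral population (trait `theta0`) on a
#' complete graph of `D` large patches (`R_nonscaffold`) for a burn-in
#' `T0`, switches every patch's replenishment target to the small scaffolded
#' endowment (`R_scaffold`) for a duration `T`, reverts to `R_nonscaffold`,
#' and runs for `t_post` further time units. The endpoint is classified
#' against the fitness valley of the non-scaffolding landscape: replicates
#' whose mean trait remains beyond the valley have endogenised coordination.
#'
#' Environment switches change the replenishment target only; a patch's
#' current stock is consumed before the new endowment applies (set
#' `reset_resources = TRUE` to cap stocks immediately at the switch).
#'
#' @param T0 burn-in duration in the non-scaffolding environment.
#' @param T_scaffold scaffold duration.
#' @param R_nonscaffold,R_scaffold patch endowments of the two environments.
#' @param theta0 ancestral trait value.
#' @param replicates number of independent replicates.
#' @param base_seed seed of replicate `i` is `base_seed + i - 1`.
#' @param D number of patches in the complete graph.
#' @param t_post duration of the post-reversion segment.
#' @param n_seed_patches patches seeded with one founder each at `t = 0`.
#' @param mutation_prob,mutation_sd mutation parameters (see [sim_config()]).
#' @param model trait model (density-dependent by default; the intrinsic
#'   model is the no-endogenisation control).
#' @param reset_resources cap patch stocks at the new endowment immediately
#'   on an environment switch (default `FALSE`).
#' @return An object of class `scaffold_result`: list with `results` (data
#'   frame `replicate`, `seed`, `theta_end`, `endpoint`, `endogenised`),
#'   `fraction_endogenised`, `paths` (list of per-replicate mean-trait time
#'   series) and the experiment parameters.
#' @export
run_temporary_scaffolding <- function(T0, T_scaffold,
                                      R_nonscaffold = 100, R_scaffold = 20,
                                      theta0 = 0.5, replicates = 20,
                                      base_seed = 1, D = 100,
                                      t_post = 3000, n_seed_patches = 10,
                                      mutation_prob = 0.01, mutation_sd = 0.05,
                                      model = "density_dependent",
                                      reset_resources = FALSE) {
  stopifnot(T0 >= 0, T_scaffold >= 0, t_post >= 0)
  model <- as_trait_model(model)
  ess_ns <- find_ess(model, R_nonscaffold)
  g_ns <- build_complete_graph(D, R_nonscaffold)
  g_sc <- build_complete_graph(D, R_scaffold)
  snap <- max(1, (T0 + T_scaffold + t_post) / 200)

  one <- function(seed) {
    state <- init_metapop(g_ns, seq_len(min(n_seed_patches, D)), theta0)
    segs <- list(list(g = g_ns, t = T0, seed = seed),
                 list(g = g_sc, t = T_scaffold, seed = NULL),
                 list(g = g_ns, t = t_post, seed = NULL))
    path <- NULL
    for (s in segs) {
      if (s$t <= 0) next
      if (reset_resources) state$resources <- pmin(state$resources, s$g$R)
      cfg <- sim_config(model, t_end = s$t, mutation_prob = mutation_prob,
                        mutation_sd = mutation_sd, seed = s$seed,
                        snapshot_interval = snap)
      sim <- run_gillespie(cfg, s$g, state)
      state <- sim$final_state
      path <- rbind(path, summarise_sim(sim))
    }
    theta_end <- mean(unlist(state$thetas))
    list(theta_end = theta_end, path = path)
  }

  seeds <- base_seed + seq_len(replicates) - 1L
  runs <- lapply(seeds, one)
  theta_end <- vapply(runs, function(r) {
    if (is.null(r$theta_end) || is.nan(r$theta_end)) NA_real_ else r$theta_end
  }, numeric(1))
  endpoint <- vapply(theta_end, function(te) {
    if (is.na(te)) NA_character_ else
      classify_endpoint(te, model, R_nonscaffold, ess = ess_ns)
  }, character(1))
  endog <- endpoint == "coordinated_branch"
  results <- data.frame(replicate = seq_len(replicates), seed = seeds,
                        theta_end = theta_end, endpoint = endpoint,
                        endogenised = endog)
  structure(list(results = results,
                 fraction_endogenised = mean(endog, na.rm = TRUE),
                 paths = lapply(runs, `[[`, "path"),
                 T0 = T0, T_scaffold = T_scaffold,
                 R_nonscaffold = R_nonscaffold, R_scaffold = R_scaffold,
                 model = model$kind,
                 valley = if (nrow(ess_ns$valleys)) ess_ns$valleys$theta[1] else NA_real_),
            class = "scaffold_result")
}

#' @export
print.scaffold_result <- function(x, ...) {
  cat(sprintf("<scaffold_result> %s model, T0 = %g, T = %g, %d replicates\n",
              x$model, x$T0, x$T_scaffold, nrow(x$results)))
  cat(sprintf("  fraction endogenised: %.2f\n", x$fraction_endogenised))
  invisible(x)
}

#' Fraction endogenised as a function of scaffold duration
#'
#' Runs [run_temporary_scaffolding()] over a grid of scaffold durations with
#' paired seeds (replicate `i` uses the same seed at every duration, so the
#' duration effect is not confounded with the seed draw).
#'
#' @param T_values vector of scaffold durations.
#' @param T0 burn-in duration shared by all runs.
#' @param ... passed to [run_temporary_scaffolding()].
#' @return data frame `T_scaffold`, `fraction_endogenised`, plus a
#'   `runs` attribute holding the individual `scaffold_result`s.
#' @export
scaffold_duration_sweep <- function(T_values, T0 = 200, ...) {
  runs <- lapply(T_values, function(Tv)
    run_temporary_scaffolding(T0 = T0, T_scaffold = Tv, ...))
  out <- data.frame(T_scaffold = T_values,
                    fraction_endogenised =
                      vapply(runs, `[[`, numeric(1), "fraction_endogenised"))
  attr(out, "runs") <- runs
  out
}

#' Goldilocks-zone gradient experiment
#'
#' A layered resource gradient (richest layer first) is seeded with
#' ancestral particles in the richest patches and simulated. Three phases
#' are detected from the per-layer snapshot series:
#' 1. occupation spreads down the gradient to the viability bound `R0`
#'    (the poorest endowment class that sustains occupation);
#' 2. layers below the fold evolve toward perfect coordination while rich
#'    layers stay near the anti-coordinated peak — coordination first
#'    appears in resource-poor layers;
#' 3. coordinated particles disperse back up and take over the rich layers.
#'
#' @param R_values strictly decreasing layer endowments (richest first).
#' @param patches_per_class patches per layer.
#' @param theta0 ancestral trait seeded in the richest layer.
#' @param t_end simulation horizon.
#' @param seed RNG seed.
#' @param mutation_prob,mutation_sd mutation parameters.
#' @param model trait model.
#' @param snapshot_interval snapshot spacing.
#' @param coord_threshold per-layer mean trait above which the layer counts
#'   as coordinated (default 0.9).
#' @param occupancy_threshold fraction of a layer's patches that must be
#'   occupied on average for the layer to count as populated (default 0.2).
#' @param R0_window time window (start, end) over which the pre-evolution
#'   viability bound `R0` is measured; defaults to an early slice of the run
#'   (`t_end/30` to `t_end/10`), after the initial expansion down the
#'   gradient but before coordination evolves and widens the range.
#' @param fold_R optional fold location `R*` (e.g. from
#'   [fold_bifurcation_scan()]). When supplied, the phase report also gives
#'   the first coordination event restricted to the Goldilocks band
#'   (`R < fold_R`), where the landscape is monostable and coordination is
#'   deterministically selected; layers just above the fold have a shallow
#'   valley that small populations can also drift across.
#' @return An object of class `gradient_result`: list with `per_layer` (data
#'   frame `time`, `layer_R`, `occupied`, `particles`, `mean_theta`),
#'   `phases` (list `R0`, `first_coordination_time`, `first_coordination_R`,
#'   `back_invasion_time`) and `counters`.
#' @export
run_goldilocks_gradient <- function(R_values = seq(100L, 3L),
                                    patches_per_class = 10,
                                    theta0 = 0.5, t_end = 4000, seed = 1,
                                    mutation_prob = 0.01, mutation_sd = 0.05,
                                    model = "density_dependent",
                                    snapshot_interval = t_end / 200,
                                    coord_threshold = 0.9,
                                    occupancy_threshold = 0.2,
                                    R0_window = t_end * c(1 / 30, 1 / 10),
                                    fold_R = NULL) {
  model <- as_trait_model(model)
  graph <- build_gradient_graph(R_values, patches_per_class)
  rich <- which(graph$layer == max(graph$layer))
  state <- init_metapop(graph, rich, theta0)
  if (!length(rich)) stop("seeded layer is empty", call. = FALSE)
  cfg <- sim_config(model, t_end = t_end, mutation_prob = mutation_prob,
                    mutation_sd = mutation_sd, seed = seed,
                    snapshot_interval = snapshot_interval)
  sim <- run_gillespie(cfg, graph, state)

  s <- sim$snapshots
  key <- interaction(s$time, s$layer_R, drop = TRUE)
  particles <- tapply(s$n, key, sum)
  occupied <- tapply(s$n > 0, key, sum)
  wtheta <- tapply(ifelse(is.na(s$mean_theta), 0, s$mean_theta * s$n), key, sum)
  parts <- do.call(rbind, strsplit(names(particles), ".", fixed = TRUE))
  per_layer <- data.frame(time = as.numeric(parts[, 1]),
                          layer_R = as.integer(parts[, 2]),
                          occupied = as.vector(occupied),
                          particles = as.vector(particles),
                          mean_theta = as.vector(wtheta) /
                            ifelse(particles > 0, particles, NA))
  per_layer <- per_layer[order(per_layer$time, -per_layer$layer_R), ]
  rownames(per_layer) <- NULL

  # phase 1: viability bound R0 over the early, pre-evolution window
  early <- per_layer[per_layer$time >= R0_window[1] &
                       per_layer$time <= R0_window[2], ]
  occ_frac <- tapply(early$occupied / patches_per_class, early$layer_R, mean)
  populated <- as.integer(names(occ_frac))[occ_frac >= occupancy_threshold]
  R0 <- if (length(populated)) min(populated) else NA_integer_

  # phase 2: first layer to reach coordination
  coord <- per_layer[!is.na(per_layer$mean_theta) &
                       per_layer$mean_theta > coord_threshold &
                       per_layer$particles >= 2, ]
  first_t <- if (nrow(coord)) min(coord$time) else NA_real_
  first_R <- if (nrow(coord)) {
    at <- coord[coord$time == first_t, ]
    as.integer(at$layer_R[which.min(at$layer_R)])
  } else NA_integer_

  # phase 2, restricted to the Goldilocks band when the fold is known
  gz_t <- gz_R <- NULL
  if (!is.null(fold_R)) {
    gz <- coord[coord$layer_R < fold_R, ]
    gz_t <- if (nrow(gz)) min(gz$time) else NA_real_
    gz_R <- if (nrow(gz)) {
      at <- gz[gz$time == gz_t, ]
      as.integer(at$layer_R[which.min(at$layer_R)])
    } else NA_integer_
  }

  # phase 3: back-invasion of the richest layer
  richest <- per_layer[per_layer$layer_R == max(R_values) &
                         !is.na(per_layer$mean_theta) &
                         per_layer$mean_theta > coord_threshold, ]
  back_t <- if (nrow(richest)) min(richest$time) else NA_real_

  structure(list(per_layer = per_layer,
                 phases = list(R0 = R0,
                               first_coordination_time = first_t,
                               first_coordination_R = first_R,
                               first_coordination_goldilocks_time = gz_t,
                               first_coordination_goldilocks_R = gz_R,
                               back_invasion_time = back_t),
                 counters = sim$counters, final_state = sim$final_state,
                 R_values = R_values, model = model$kind, t_end = t_end),
            class = "gradient_result")
}

#' @export
print.gradient_result <- function(x, ...) {
  cat(sprintf("<gradient_result> %s model, %d layers, t_end = %g\n",
              x$model, length(x$R_values), x$t_end))
  ph <- x$phases
  cat(sprintf("  viability bound R0: %s\n", ph$R0))
  cat(sprintf("  coordination first at t = %s in layer R = %s\n",
              format(ph$first_coordination_time), ph$first_coordination_R))
  cat(sprintf("  back-invasion of richest layer at t = %s\n",
              format(ph$back_invasion_time)))
  invisible(x)
}
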