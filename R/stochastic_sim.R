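#' Complete patch graph
#'
#' Every patch is adjacent to every other patch; all patches share the same
#' resource endowment.
#'
#' @param D number of patches (>= 1).
#' @param R resource endowment of every patch.
#' @return An object of class `metapop_graph`: list with `D`, `adj` (list of
#'   integer neighbour vectors, 1-based), `R` (per-patch endowment) and
#'   `layer` (resource class of each patch).
#' @export
build_complete_graph <- function(D, R) {
  if (D < 1 || D != floor(D)) stop("`D` must be a positive integer", call. = FALSE)
  if (R < 1 || R != floor(R)) stop("`R` must be a positive integer", call. = FALSE)
  adj <- lapply(seq_len(D), function(i) setdiff(seq_len(D), i))
  structure(list(D = as.integer(D), adj = adj,
                 R = rep(as.integer(R), D), layer = rep(as.integer(R), D)),
            class = "metapop_graph")
}

#' Layered resource-gradient patch graph
#'
#' Patches are organised in richness classes (layers). Each layer is
#' internally complete, and every patch is additionally adjacent to all
#' patches of the next richer and next poorer layer; dispersal cannot skip
#' layers.
#'
#' @param R_values strictly decreasing integer vector of per-layer resource
#'   endowments (richest first).
#' @param patches_per_class number of patches in each layer.
#' @return A `metapop_graph` with `layer` recording each patch's endowment
#'   class.
#' @export
build_gradient_graph <- function(R_values, patches_per_class = 10) {
  if (length(R_values) < 1) stop("need at least one layer", call. = FALSE)
  if (any(diff(R_values) >= 0)) {
    if (length(R_values) > 1) stop("`R_values` must be strictly decreasing", call. = FALSE)
  }
  if (any(R_values < 1) || any(R_values != floor(R_values))) {
    stop("`R_values` must be positive integers", call. = FALSE)
  }
  m <- as.integer(patches_per_class)
  if (m < 1) stop("`patches_per_class` must be >= 1", call. = FALSE)
  L <- length(R_values)
  D <- L * m
  layer_of <- rep(seq_len(L), each = m)
  ids_by_layer <- split(seq_len(D), layer_of)
  adj <- vector("list", D)
  for (l in seq_len(L)) {
    reach <- unlist(ids_by_layer[intersect(c(l - 1L, l, l + 1L), seq_len(L))],
                    use.names = FALSE)
    for (i in ids_by_layer[[l]]) adj[[i]] <- setdiff(reach, i)
  }
  structure(list(D = D, adj = adj,
                 R = rep(as.integer(R_values), each = m),
                 layer = rep(as.integer(R_values), each = m)),
            class = "metapop_graph")
}

#' @export
print.metapop_graph <- function(x, ...) {
  cat(sprintf("<metapop_graph> %d patches, %d resource class(es)\n",
              x$D, length(unique(x$layer))))
  invisible(x)
}

#' Initial meta-population state
#'
#' @param graph a `metapop_graph`.
#' @param seed_patches indices of patches to seed with one founding particle
#'   each.
#' @param theta0 founding trait value (single value or one per seeded patch).
#' @return An object of class `metapop_state`: list with `resources`
#'   (per-patch stock) and `thetas` (list of per-patch trait vectors) and
#'   `time`.
#' @export
init_metapop <- function(graph, seed_patches, theta0 = 0.5) {
  stopifnot(inherits(graph, "metapop_graph"))
  check_theta(theta0)
  if (any(seed_patches < 1 | seed_patches > graph$D)) {
    stop("`seed_patches` out of range", call. = FALSE)
  }
  theta0 <- rep_len(theta0, length(seed_patches))
  thetas <- rep(list(numeric(0)), graph$D)
  for (k in seq_along(seed_patches)) {
    thetas[[seed_patches[k]]] <- c(thetas[[seed_patches[k]]], theta0[k])
  }
  structure(list(resources = graph$R, thetas = thetas, time = 0),
            class = "metapop_state")
}

#' Simulation configuration
#'
#' @param model a [trait_model()] or its kind as a string.
#' @param t_end simulation horizon (time units of the particle consumption
#'   rate).
#' @param mutation_prob per-duplication probability that the offspring trait
#'   mutates (default 0.01).
#' @param mutation_sd standard deviation of the Gaussian trait perturbation
#'   (default 0.05); mutated traits are clipped to `[0, 1]`.
#' @param seed integer seed; `NULL` to continue the current RNG stream (used
#'   when chaining runs across environment changes).
#' @param snapshot_interval spacing of state snapshots; 0 disables snapshots.
#' @param dispersal `"uniform"` (default): a propagule targets a uniformly
#'   random adjacent patch and dies on arrival when that patch is occupied —
#'   the rule whose mean field is the occupancy ODE. `"empty_only"`: the
#'   target is uniform among currently empty adjacent patches and the
#'   propagule dies only when none exists.
#' @param replenish_on_empty replenish a patch vacated by dispersal
#'   immediately (default `TRUE`); otherwise only depletion replenishes.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(model, t_end, mutation_prob = 0.01, mutation_sd = 0.05,
                       seed = NULL, snapshot_interval = t_end / 100,
                       dispersal = c("uniform", "empty_only"),
                       replenish_on_empty = TRUE) {
  model <- as_trait_model(model)
  dispersal <- match.arg(dispersal)
  stopifnot(t_end >= 0, mutation_prob >= 0, mutation_prob <= 1,
            mutation_sd > 0, snapshot_interval >= 0)
  structure(list(model = model, t_end = t_end, mutation_prob = mutation_prob,
                 mutation_sd = mutation_sd, seed = seed,
                 snapshot_interval = snapshot_interval, dispersal = dispersal,
                 replenish_on_empty = replenish_on_empty),
            class = "sim_config")
}

#' Run the exact event-driven simulation
#'
#' Simulates the meta-population Markov jump process on an arbitrary patch
#' graph: exponential waiting times at total rate equal to the particle
#' count, uniform choice of the acting particle, duplication with probability
#' `p(theta, n)` (with rare Gaussian mutation of the offspring trait) or
#' dispersal to a connected patch otherwise, instant patch death and
#' replenishment on depletion. Identical `(config, graph, init)` with the
#' same seed give identical output.
#'
#' @param config a [sim_config()].
#' @param graph a `metapop_graph`.
#' @param init a `metapop_state`, e.g. from [init_metapop()] or the
#'   `final_state` of a previous run (chaining preserves the RNG stream when
#'   `config$seed` is `NULL`).
#' @return An object of class `metapop_sim`: list with `snapshots` (data
#'   frame `time`, `patch`, `layer_R`, `n`, `r`, `mean_theta`), `final_state`
#'   (a `metapop_state`), and `counters` (events, propagules emitted,
#'   colonisations, propagule deaths; emissions = colonisations + deaths).
#' @export
run_gillespie <- function(config, graph, init) {
  stopifnot(inherits(config, "sim_config"), inherits(graph, "metapop_graph"),
            inherits(init, "metapop_state"))
  if (!is.null(config$seed)) set.seed(config$seed)
  t0 <- init$time
  out <- .sim_gillespie_cpp(
    graph$adj, as.integer(graph$R), config$model$kind == "density_dependent",
    as.integer(init$resources), init$thetas,
    config$mutation_prob, config$mutation_sd,
    t0, t0 + config$t_end, config$snapshot_interval,
    config$dispersal == "uniform", config$replenish_on_empty)
  snapshots <- data.frame(time = out$snap_time, patch = out$snap_patch,
                          layer_R = graph$layer[out$snap_patch],
                          n = out$snap_n, r = out$snap_r,
                          mean_theta = out$snap_mean_theta)
  final_state <- structure(list(resources = out$resources,
                                thetas = out$thetas, time = out$time),
                           class = "metapop_state")
  structure(list(snapshots = snapshots, final_state = final_state,
                 counters = c(events = out$events,
                              propagules_emitted = out$propagules_emitted,
                              colonisations = out$colonisations,
                              propagule_deaths = out$propagule_deaths),
                 config = config),
            class = "metapop_sim")
}

#' @export
print.metapop_sim <- function(x, ...) {
  cat(sprintf("<metapop_sim> t = %g, %d snapshot rows\n",
              x$final_state$time, nrow(x$snapshots)))
  cat("  counters:", paste(names(x$counters), x$counters, sep = " = ",
                           collapse = ", "), "\n")
  invisible(x)
}

#' Per-snapshot population summary
#'
#' @param sim a `metapop_sim`.
#' @return data frame with one row per snapshot time: `time`, `occupied`
#'   (patches with particles), `particles` (total count), `mean_theta`
#'   (particle-weighted mean trait).
#' @export
summarise_sim <- function(sim) {
  s <- sim$snapshots
  times <- sort(unique(s$time))
  occupied <- as.vector(tapply(s$n > 0, s$time, sum))
  particles <- as.vector(tapply(s$n, s$time, sum))
  wsum <- ifelse(is.na(s$mean_theta), 0, s$mean_theta * s$n)
  mean_theta <- as.vector(tapply(wsum, s$time, sum)) / ifelse(particles > 0, particles, NA)
  data.frame(time = times, occupied = occupied, particles = particles,
             mean_theta = mean_theta)
}

#' Write simulation snapshots to CSV
#' @param sim a `metapop_sim`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_snapshots_csv <- function(sim, path) {
  utils::write.csv(sim$snapshots, path, row.names = FALSE)
  invisible(path)
}
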