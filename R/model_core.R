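#' Trait models: how a particle decides between duplication and dispersal
#'
#' A particle that consumes a resource item either duplicates (producing a
#' second particle carrying the same trait) or leaves the patch as a
#' propagule. The probability of duplication, `p`, is governed by the
#' particle's heritable trait `theta` in one of two ways:
#'
#' * `"intrinsic"` — `p(theta, n) = theta` regardless of the local particle
#'   count `n`. The trait is a fixed investment in duplication versus
#'   dispersal; particles ignore their surroundings.
#' * `"density_dependent"` — `p(theta, n) = theta` when the particle is alone
#'   (`n = 1`) and `1 - theta` otherwise. The trait now encodes coordination
#'   between particles: at `theta = 1` a lone particle always duplicates and
#'   a non-lone particle always disperses (perfect coordination); at
#'   `theta = 0.5` behaviour is density-independent and the model coincides
#'   with the intrinsic model at `theta = 0.5`; at `theta = 0` particles are
#'   anti-coordinated.
#'
#' @param kind `"intrinsic"` or `"density_dependent"` (abbreviations such as
#'   `"dd"` are accepted).
#' @return An object of class `trait_model`.
#' @examples
#' m <- trait_model("density_dependent")
#' duplication_probability(m, theta = 1, n = 1)  # lone particle duplicates
#' duplication_probability(m, theta = 1, n = 5)  # crowded particle disperses
#' @export
trait_model <- function(kind = c("intrinsic", "density_dependent")) {
  if (identical(kind, "dd")) kind <- "density_dependent"
  kind <- match.arg(kind)
  structure(list(kind = kind), class = "trait_model")
}

#' @export
print.trait_model <- function(x, ...) {
  cat("<trait_model> kind:", x$kind, "\n")
  invisible(x)
}

as_trait_model <- function(model) {
  if (inherits(model, "trait_model")) model else trait_model(model)
}

#' Validate a trait value
#'
#' Traits live on `[0, 1]`: the investment toward duplication (intrinsic
#' model) or the degree of coordination (density-dependent model).
#'
#' @param theta numeric vector of candidate trait values.
#' @return `theta`, invisibly, after validation.
#' @export
check_theta <- function(theta) {
  if (!is.numeric(theta) || anyNA(theta) || any(theta < 0) || any(theta > 1)) {
    stop("trait values must be numeric in [0, 1]", call. = FALSE)
  }
  invisible(theta)
}

#' Duplication probability of a focal particle
#'
#' @param model a [trait_model()] (or its kind as a string).
#' @param theta trait value in `[0, 1]`.
#' @param n local particle count including the focal particle; must be >= 1.
#'   Vectorised over `n`.
#' @return numeric vector of probabilities, same length as `n`.
#' @export
duplication_probability <- function(model, theta, n) {
  model <- as_trait_model(model)
  check_theta(theta)
  if (length(theta) != 1L) stop("`theta` must be a single value", call. = FALSE)
  if (any(n < 1) || any(n != floor(n))) {
    stop("`n` must be a positive integer: the focal particle is in the patch",
         call. = FALSE)
  }
  switch(model$kind,
    intrinsic = rep_len(theta, length(n)),
    density_dependent = ifelse(n == 1, theta, 1 - theta)
  )
}

#' Construct a single-patch state
#'
#' A patch holds an integer stock of resources (replenished to `R` on patch
#' death) and a multiset of particle traits.
#'
#' @param R initial (and replenishment) resource endowment, a positive
#'   integer.
#' @param thetas numeric vector of resident particle traits (may be empty).
#' @param resources current resource stock; defaults to `R`.
#' @return An object of class `patch_state`.
#' @export
patch_state <- function(R, thetas = numeric(0), resources = R) {
  if (R < 1 || R != floor(R)) stop("`R` must be a positive integer", call. = FALSE)
  if (resources < 0 || resources > R) {
    stop("`resources` must lie in [0, R]", call. = FALSE)
  }
  check_theta(thetas)
  structure(list(R = as.integer(R), resources = as.integer(resources),
                 thetas = as.numeric(thetas)),
            class = "patch_state")
}

#' @export
print.patch_state <- function(x, ...) {
  cat("<patch_state> resources:", x$resources, "/", x$R,
      " particles:", length(x$thetas), "\n")
  invisible(x)
}

#' Apply one resource-consumption event to a patch
#'
#' The chosen particle consumes exactly one resource item and either
#' duplicates (offspring trait equal to the parent trait; mutation belongs to
#' the simulator layer, not here) or leaves as a propagule. If the event
#' exhausts the patch's resources, every remaining particle dies and the
#' stock is replenished to `R`. By default a patch vacated by dispersal
#' (no particles left, resources remaining) is also replenished immediately,
#' so patches are two-valued (occupied or fresh); set
#' `replenish_on_empty = FALSE` to leave a vacated patch's stock untouched
#' until its next depletion.
#'
#' @param patch a [patch_state()] with at least one resource and the chosen
#'   particle present.
#' @param particle index of the acting particle in `patch$thetas`.
#' @param outcome `"duplicate"` or `"disperse"`.
#' @param replenish_on_empty replenish a patch emptied by dispersal
#'   (default `TRUE`).
#' @return A list with elements `patch` (the new [patch_state()]) and
#'   `propagule` (the emigrant's trait value, or `NULL` when the outcome is
#'   duplication).
#' @export
apply_consumption_event <- function(patch, particle,
                                    outcome = c("duplicate", "disperse"),
                                    replenish_on_empty = TRUE) {
  outcome <- match.arg(outcome)
  stopifnot(inherits(patch, "patch_state"))
  if (patch$resources < 1) {
    stop("event on a resource-exhausted patch", call. = FALSE)
  }
  if (length(patch$thetas) < 1 || particle < 1 || particle > length(patch$thetas)) {
    stop("chosen particle is not present in the patch", call. = FALSE)
  }
  r <- patch$resources - 1L
  thetas <- patch$thetas
  propagule <- NULL
  if (outcome == "duplicate") {
    thetas <- c(thetas, thetas[particle])
  } else {
    propagule <- thetas[particle]
    thetas <- thetas[-particle]
  }
  if (r == 0L) {
    # depletion: instant death of all residents, stock replenished
    thetas <- numeric(0)
    r <- patch$R
  } else if (length(thetas) == 0L && replenish_on_empty) {
    r <- patch$R
  }
  list(patch = patch_state(patch$R, thetas, r), propagule = propagule)
}
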