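---
title: "Ecological scaffolding, endogenisation and Goldilocks zones: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ecological scaffolding, endogenisation and Goldilocks zones: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecoscaffold)
```

## The process being modelled

`ecoscaffold` implements a minimal mechanistic model of an evolutionary
transition in individuality driven by an externally imposed meta-population
structure. The lower-level units ("particles" — cells, replicating
molecules, organisms) live on a fixed graph of `D` patches, each endowed
with `R` discrete resource items. Particles consume resources at rate 1;
each consumption event either duplicates the particle or converts it into a
propagule that attempts to colonise a connected patch. Depleting a patch
kills all of its residents and replenishes the stock — this renewal is what
creates a birth–death process at the *collective* level, and with it the
opportunity for selection on collective traits.

The heritable trait `θ ∈ [0, 1]` sets the duplication probability through
one of two laws:

* **intrinsic** — `p(θ, n) = θ`. A pure investment trait; a group of such
  particles is a mere aggregate, and its collective behaviour is the sum of
  independent individual behaviours.
* **density-dependent** — `p(θ, 1) = θ`, `p(θ, n>1) = 1 − θ`. The trait now
  measures *coordination*: at `θ = 1` a lone particle always duplicates and
  a non-lone particle always disperses; at `θ = 0.5` density information is
  ignored and the model coincides with the intrinsic law at 0.5; at `θ = 0`
  particles are anti-coordinated. This is the simplest caricature of a
  sensing/regulation mechanism (quorum signal, contact inhibition, …) whose
  *presence* makes collective behaviour non-aggregative.

Three deliberate simplifications keep the model analysable; all are
structural assumptions, not parameters: particles never die inside a patch,
propagules can only found *empty* patches (a one-particle bottleneck at
collective birth), and sensing is instantaneous and error-free. The first
two remove any advantage of large standing group size, which is why perfect
coordination settles into collectives of one–two particles.

## Exact collective life history

Everything in the analysis layer rests on two collective-level quantities
for a collective founded by a single particle in a fresh patch:
`ρ(θ)`, the expected lifetime number of propagules, and `τ(θ)`, the
expected lifespan. Both are computed *exactly* by first-step analysis over
the finite state space `(n, r)` (particle count, resources left):

$$E(n,r) = p\,E(n{+}1, r{-}1) + (1-p)\,\bigl(1 + E(n{-}1, r{-}1)\bigr),$$
$$T(n,r) = \tfrac{1}{n} + p\,T(n{+}1, r{-}1) + (1-p)\,T(n{-}1, r{-}1),$$

with `E = T = 0` at `r = 0` and `n = 0`, and `ρ = E(1, R)`,
`τ = T(1, R)`. Events occur at total rate `n`, hence the mean waiting term
`1/n`; since each duplication consumes one item, `n ≤ R + 1` and the table
has `O(R²)` entries. `collective_life_history()` runs one `O(R²)` sweep;
`life_history_grid()` (internal) vectorises the same sweep across a trait
grid, which is what makes dense landscapes and the integer-`R` fold scan
cheap. The suite cross-checks the recursion two independent ways: exhaustive
enumeration of all `2^R` sample paths for small `R`, and Monte-Carlo means
of `simulate_single_patch()` at 10,000 replicates (agreement required within
four standard errors).

Useful exact anchors: `ρ(0) = τ(0) = 1` (one propagule after one mean-1
wait), `ρ(1) = 0` for the intrinsic law (the collective burns out), and for
perfect coordination `ρ = R/2`, `τ = (R/2)(1 + 1/2)` — one propagule per two
resource items, in cycles of a lone duplication (mean wait 1) followed by a
dispersal at `n = 2` (mean wait 1/2).

## Occupancy approximation and invasion analysis

On a complete graph the meta-population is summarised by the occupancy
equation

$$\frac{do}{dt} = \frac{\rho}{\tau}\,o\,\frac{D-o}{D} - \frac{o}{\tau},$$

collectives dying at rate `1/τ` and emitting propagules at rate `ρ/τ`, each
succeeding only when its uniformly drawn target patch is empty. The stable
equilibrium is `o* = D(1 − 1/ρ)` for `ρ > 1` and extinction otherwise:
viability is exactly `ρ(θ) > 1`. `τ` rescales time but not the equilibrium.

**The dispersal target rule is the one genuinely open design choice.** If a
propagule could search for *any* empty patch (and die only when none
exists), a complete-graph meta-population would saturate to `o ≈ D` for
every `ρ > 1`, and occupancy would carry no information about `ρ`. For the
occupancy equation above to be the mean field of the simulator, the
propagule must commit to one uniformly random adjacent patch and die if it
is occupied. We therefore made dead-on-arrival-if-occupied the default
(`dispersal = "uniform"` in `sim_config()`), keeping the search variant
available as `"empty_only"`. With the default, a `D = 200` complete-graph
simulation reproduces `o*` to within replicate noise (the suite requires
three standard errors).

A rare mutant in the resident's equilibrium environment (empty-patch
fraction `e* = 1/ρ(θ_res)`) grows at rate

$$s(\theta_m, \theta_r) = \frac{\rho(\theta_m)\,e^* - 1}{\tau(\theta_m)}
 = \frac{\rho(\theta_m)/\rho(\theta_r) - 1}{\tau(\theta_m)},$$

so `sign(s) = sign(ρ_m − ρ_r)`: pairwise invasibility, ESS location and
convergence stability all reduce to the one-dimensional `ρ(θ)` landscape,
and `find_ess()` works by locating its stationary points. Interior extrema
are detected on a `10⁻³` grid by finite-difference sign changes and refined
by golden-section search on the exact recursion (tolerance `10⁻³` in `θ`);
the boundary `θ = 1` is an ESS when `ρ` increases into it. Reported
positions at `R = 100`: anti-coordinated ESS at `θ = 0.418`, valley at
`θ = 0.665`, plus the boundary ESS — i.e. a bistable landscape.

Two landscape subtleties deserve a note:

* **Viability restriction.** The density-dependent landscape has a very
  shallow interior minimum near `θ ≈ 0.01–0.03` at all `R`, entirely inside
  the non-viable region `ρ < 1`. Extremum counting (in `rho_curve()`,
  `find_ess()` and `fold_bifurcation_scan()`) is therefore restricted to
  `ρ > 1`: a feature of the landscape that no persisting population can
  occupy is not an evolutionary attractor or repellor.
* **Fold tie-break.** The interior max/min pair of the viable landscape is
  absent for `R ≤ 39` and present for `R ≥ 40` (at `R = 40` the pair sits
  near `θ ≈ 0.54/0.58`, well above grid resolution). `R*` is reported as the
  *largest* `R` without the pair, i.e. `R* = 39`, so "valley exists" reads
  `R > R*`.

`trait_substitution_trajectory()` implements mutation-limited evolution as
a gradient-following walk: `Δθ = 10⁻³` per substitution, direction
`sign(dρ/dθ)` (central difference, step `10⁻³`), stopping at a boundary, at
`|dρ/dθ| < 10⁻⁸`, or when the walk starts oscillating around a peak (the
endpoint is then within one step of the attractor). The endogenisation test
`check_endogenisation_conditions()` phrases the three formal conditions
directly on these objects: (1) two ESSs and a valley in the ancestral
environment, (2) no scaffold-environment ESS within 0.05 of the
ancestral-side ESS, (3) the scaffold attractor reached from `θ₀` lies
beyond the ancestral valley.

## The stochastic simulator

`run_gillespie()` is an exact event-driven implementation of the jump
process (C++ core): exponential waiting times at total rate equal to the
particle count, uniform particle choice via a Fenwick tree over patches,
one resource consumed per event, instant patch death and replenishment at
depletion. Determinism is part of the contract: identical configuration and
seed give bit-identical output, and chained runs (environment switches)
continue a single RNG stream.

Choices the underlying description leaves open, and the defaults here:

* **Vacated patches.** Only depletion is specified to trigger
  replenishment. A patch emptied by dispersal while resources remain is
  replenished immediately by default (`replenish_on_empty = TRUE`), keeping
  patch state two-valued (fresh or occupied) exactly as the occupancy
  equation assumes — every colonist founds a collective at `(n = 1, r = R)`,
  matching the life-history computation. The alternative (leftover stock
  persists) is available as a switch.
* **Mutation kernel.** Unspecified in the source model beyond "rare and
  small". Default: with probability `μ = 0.01` per duplication the offspring
  trait gains a `N(0, 0.05²)` perturbation, clipped to `[0, 1]`. These
  values keep the adaptive-dynamics separation of timescales approximately
  valid (populations reach ecological quasi-equilibrium between sweeps)
  while letting desk-scale runs finish in seconds.
* **Environment switches** change each patch's replenishment *target*; the
  current stock is consumed first (configurable to an immediate cap via
  `reset_resources` in `run_temporary_scaffolding()`).

## Experiments and their parameters

**Temporary scaffolding** (`run_temporary_scaffolding()`): `D = 100`
complete graph, burn-in `T₀` at `R = 100`, scaffold at `R = 20` for `T`,
reversion for `t_post`. Endpoints are classified against the *computed*
valley position (`classify_endpoint()`), never a hard-coded threshold. At
the default mutation parameters the population settles near the
anti-coordinated ESS within `t ≈ 400`, and under the scaffold crosses the
valley in roughly `T ≈ 400–1100` depending on the replicate — which is why
the duration sweep uses `T ∈ {0, 400, 800, 2000}`: `T = 0` never
endogenises, `T = 2000` always does, intermediate values split across
replicates exactly as a stochastic valley-crossing should.

**Goldilocks gradient** (`run_goldilocks_gradient()`): 98 layers from
`R = 100` down to `R = 3` (the seeded `R = 100` layer plus 97 poorer
classes), 10 patches per layer, within-layer complete and adjacent layers
fully interconnected. Ancestral particles (`θ₀ = 0.5`) are seeded in the
richest layer. Phase markers:

* `R0` — the poorest layer sustaining ≥ 20% mean occupancy over an *early*
  window (`t_end/30` to `t_end/10`). Measured early because after
  coordination evolves, the ecological range widens (that is the point of
  the Goldilocks effect); a late measurement would report the derived
  range, not the ancestral viability bound. The measured `R0 = 4` matches
  the analytic bound (`ρ(0.5, 3) = 1` exactly; `> 1` from `R = 4`).
* first coordination — earliest snapshot with a layer mean trait above 0.9
  (at least two particles). When the fold `R*` is supplied, the marker is
  also reported restricted to the Goldilocks band `R < R*`, where
  coordination is deterministically selected. Layers just *above* the fold
  have a shallow valley that a ten-patch population can also drift across,
  so the unrestricted marker occasionally fires first in a mid-rich layer;
  the robust, reproducible ordering — Goldilocks-band coordination while
  the richest layer is still ancestral, followed by back-invasion — is what
  the tests assert.
* back-invasion — earliest snapshot with the richest layer's mean trait
  above 0.9.

## What the simulations do and do not show

The simulator emulates exactly the idealised process the analysis layer
describes — and nothing more. Passing tests therefore demonstrate internal
consistency of the stochastic process, its mean field, and the
adaptive-dynamics reduction at the stated scales (`D` of order 100–1000,
`t` of order 10³–10⁴ consumption times, 4–20 replicates). They do not show
robustness to features the model deliberately omits: within-patch particle
death, colonisation of occupied patches (migratory mixing), sensing noise
or delays (relaxing these enlarges collectives and erodes the hysteresis),
non-Gaussian or non-rare mutation, or demographic rates that differ between
duplication and dispersal. The fold location `R* = 39` and the landscape
positions are exact properties of the model, but their two-decimal
reporting (`0.42`, `0.67`) reflects the `10⁻³` refinement tolerance, not
measurement uncertainty.

## Degenerate inputs and numerical conventions

Trait values outside `[0, 1]`, `R < 1`, events on empty or exhausted
patches, non-monotone gradient layer lists, and trait grids with fewer than
three points or non-increasing spacing all raise errors at construction.
`equilibrium_occupancy()` returns 0 (not a negative root) for `ρ ≤ 1`;
`solve_theta_max()` brackets the root between the landscape's global
maximiser and 1 and reports 1 when the model stays viable to the boundary
(the density-dependent case). All randomness flows through R's RNG — seeds
set in R propagate into the C++ core — so every stochastic result in the
documentation and tests is reproducible from its stated seed.
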