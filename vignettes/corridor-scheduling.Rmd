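---
title: "Scheduling climate-change corridors: models, synthetic data and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scheduling climate-change corridors: models, synthetic data and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cccplan)
```

This vignette is the package's own account of the science it implements:
the corridor model and its assumptions, what the synthetic landscape
generator does and does not emulate, the two optimisation models and how
they are solved exactly, the factorial experiment, the effects analysis,
and every numerical choice a user might want to question.

## 1. The corridor model

A landscape is a regular planar grid of cells (centroids in km), observed
over `T` planning periods (default four 30-year periods). Each species
carries a suitability surface `pos(i, t)` in [0, 1] per period, and a
maximum per-period dispersal distance `d_max`. A *climate-change corridor*
for a species is a time-ordered cell sequence `u1, ..., uT`, one cell per
period; its persistence score is the product of the per-period suitability
values and the between-period dispersal success probabilities:

$$P_{sc} = \mathrm{pos}_{u_1,1} \cdot \mathrm{pds}_{u_1,u_2} \cdot
\mathrm{pos}_{u_2,2} \cdots \mathrm{pds}_{u_{T-1},u_T} \cdot
\mathrm{pos}_{u_T,T}.$$

The product form makes persistence multiplicative in risk: one
nonfunctional cell (`pos = 0`) or one infeasible transition (`pds = 0`)
voids the corridor. Scores are not calibrated probabilities of persistence;
they are comparable *within* a species and scenario, which is all the
selection models need.

Assumptions worth stating plainly:

- **Dispersal is geometric, not functional.** Success depends only on
  Euclidean centroid distance, via a negative-exponential kernel
  `pds(d) = exp(-alpha d)` truncated to 0 beyond `d_max`. The kernel family
  is a deliberate choice: the calibration convention fixes `pds(0) = 1` and
  the success at `d_max` (5%, 10% or 15% for the α1/α2/α3 curves), and the
  negative exponential is the standard one-parameter kernel satisfying
  both. Habitat permeability, barriers and land-use friction are out of
  scope.
- **Within-period dynamics are not modelled.** There are no colonisation
  or extinction rates inside a period; the corridor either works or it
  does not.
- **The non-dispersal case** is modelled as staying in place with
  certainty (self-edges of weight 1), so persistence reduces to the product
  of suitabilities of one fixed cell. Any alternative normalisation of the
  stay-probability would rescale all corridors of a species equally and
  change no selection.
- **Anthropogenic exclusion** removes cells whose human-footprint index
  exceeds 60 (urban landscapes) from all periods before any analysis. The
  boundary is inclusive: exactly 60 is retained. The filter consumes a
  precomputed per-cell index; how that index was aggregated from finer
  rasters is upstream of this package.

## 2. Candidate corridors: exact top-K enumeration

Optimising over all `n^T` corridors is hopeless at landscape scale, so
selection works on a preprocessed candidate set per species: the K
highest-persistence corridors (default `K = 2000`). Unlike heuristic
prefilters, `enumerate_candidates()` computes the *exact* top K by dynamic
programming over the time-layered DAG: each (cell, period) node keeps its K
best incoming partial paths, accumulated in log space; the final layer is
merged and backtracked. Exactness matters for testing — results are
reproducible and provably cannot be improved by a better preprocessing —
and can only improve solution quality relative to a sampling heuristic.

Numerical choices:

- Scores accumulate as sums of logs; `exp` is applied once at the end.
  Tests confirm agreement with direct products to 1e-12 relative.
- Exact score ties break lexicographically by cell sequence, so output is
  platform-independent.
- Zero-persistence corridors are excluded outright; a species with no
  positive-persistence corridor is reported unprotectable (empty set with a
  warning) and enters results with persistence 0.

## 3. The selection models and the exact solver

**maxPers** (single species): choose a subset of candidates, pairwise
*independent* (no two corridors of the species use the same cell in the
same period), maximising summed persistence, with the cost of the union of
used (cell, period) units within the budget `B`.

**minShortfall** (multi-species): given strictly positive per-species
targets `T_s`, minimise `sum_s max(0, (T_s - achieved_s) / T_s)` under the
same independence and budget constraints. Proportional shortfalls keep
species with persistence scores of different orders of magnitude
commensurable. Shortfalls are floored at zero: exceeding a target earns no
credit.

Design choices made where the problem statement is genuinely open:

- **Shared cells are paid once across species.** Conserving an area at a
  time serves every species present; this is also the reading under which
  the minimum cost of a single four-period corridor under a uniform layer
  is exactly 4 (the budget sweep's first value).
- **Independence binds within species only.** Corridors of different
  species may co-occupy a cell-period.
- **No species weights** in the multi-species objective (equal weights;
  weighting is a straightforward extension of the objective but is not a
  default behaviour).

No mixed-integer-programming library is a dependency: the solver
(`src/ccc_solver.cpp`) is a purpose-built exact branch-and-bound. It
branches on candidates in root density order and prunes with two admissible
upper bounds: (i) the target-capped sum of all remaining compatible
persistence, ignoring the budget; and (ii) a fractional-knapsack bound in
which each candidate's marginal cost is deflated by the across-species
multiplicity of its cell-periods — a provable lower bound on the cost any
completion pays, so the bound never cuts the optimum. Optimality is proved
by exhaustion of the search tree (tolerance 1e-12); tests verify agreement
with an exhaustive-subset oracle on hundreds of seeded micro-instances. A
node cap (default 1e7) guards against pathological inputs and raises an
error rather than returning a silent approximation.

Tie-breaking: the brute-force oracle prefers the lexicographically smallest
candidate index set among optima; the branch-and-bound returns one optimum
deterministically but not necessarily that one, so tests compare objective
values, never selections.

## 4. The synthetic study generator

The package is fully testable without any downloaded data: `make_study()`
generates landscapes with the statistical structure the analysis assumes.

- **Suitability**: each species has a Gaussian niche
  (`peak * exp(-d^2 / (2 width^2))`), whose centre drifts at the scenario's
  `shift_velocity` (km/period, direction drawn once per species) and whose
  height erodes by `(1 - erosion)` per period, plus seeded Gaussian noise
  (sd 0.02), clipped to [0, 1]. Baseline cells below an occupancy cutoff
  (default `pos < 0.05`) are zeroed, emulating cells with no species
  records at the baseline period.
- **Scenarios**: no-change (0, 0); moderate change (6 km/period, 8%
  erosion); severe change (12 km/period, 16%). The severity *ordering* is
  what downstream properties rely on (a sedentary species' best corridor is
  strictly worse under the severe scenario than under no change); the
  magnitudes were chosen once as a realistic displacement of roughly one to
  five cell widths over the 90-year horizon, and are configurable.
- **Costs**: per activity, a spatially autocorrelated opportunity-cost
  field (Gaussian smoothing of seeded white noise, range 25 km,
  exponentiated to stay positive, unit mean), with a multiplicative 5%
  per-period trend; plus a `uniform` layer of exactly 1 per cell-period and
  a `total` layer summing all activities.
- **Prevalence**: species' `prevalence_scale` spans two orders of
  magnitude, reproducing the large spread in summed baseline suitability
  between common and rare species.
- **Footprint**: a configurable fraction of cells (default 5%) receives an
  index above 60 and is removed by the filter.

Everything is deterministic given `(config, seed)` — including bit-identical
CSV serialisation — with per-species subseeds shared across scenarios so
that scenarios differ *only* through shift and erosion.

What the generator does **not** emulate: real geography and coastline
effects, ensemble niche-model uncertainty, correlated multi-species niches,
land-use storylines with spatial policy structure, or fat-tailed dispersal.
Passing tests on synthetic landscapes therefore demonstrate correctness of
the machinery and the direction of the main effects, not empirical claims
about any real region.

## 5. The factorial experiment

`build_design()` expands the factor grid. At full scale — 10 species × 3
climate scenarios × 4 dispersal levels × 6 conflict layers × 400 budgets
(4, 8, …, 1600) — the single-species design counts 288,000 runs and the
multi-species design 28,800; the package reproduces these counts as a pure
accounting operation. `run_ss()` executes the dedicated-plan sweep and its
optima become the targets of `run_ms()` at matching factor combinations.
Candidate sets depend only on suitability and dispersal, so they are
computed once per (species, climate, dispersal) and reused across all
budgets and conflict layers.

The shipped demonstration study is desk-scale: a 20 × 20 grid of 10-km
cells, 5 species, 3 scenarios, 4 dispersal levels, the uniform and total
conflict layers, and a 10-budget sweep (4, 8, …, 40) with `K = 12`
candidates per species — sized so that the full SS→MS experiment and its
property checks (persistence monotone in budget, multi-species never beating
the dedicated optimum, summed relative shortfall decaying with budget) run
in seconds while exercising every code path at paper-shaped factor levels.

## 6. The effects analysis

Per species, persistence is modelled as
`persistence ~ design + climate + dispersal + conflict + (1 | budget)`:
additive fixed effects (no interactions), budget levels as a random
intercept. REML estimation via lme4; factors with one observed level are
dropped; a singular fit (variance component at 0) is downgraded to a
warning. Variance explained is partitioned the standard way:
`R2m = Vfix / (Vfix + Vrand + Vres)` and
`R2c = (Vfix + Vrand) / (Vfix + Vrand + Vres)`, with `Vfix` the variance of
the fixed-effects linear predictor.

Effect sizes: for factor `F`, each level's estimate is the balanced
marginal mean (other factors averaged with equal weight over their levels —
the paper-style "covariates at their means", made precise; computed from
the treatment-contrast coefficients and cross-checked against emmeans with
equal weights). `PeffFm` is the mean of the level estimates, `PeffFd` their
range, and the effect size is the scale-free ratio
`Peff = PeffFd / PeffFm`, undefined (an error, with diagnostics) when the
marginal mean is not positive. The response is left untransformed — the
ratio form of `Peff` absorbs scale differences between species.

Two derived comparisons: `ms_ss_ratio()` (fraction of the dedicated-plan
persistence retained in the joint plan, in [0, 1] by construction) and
`climate_effect_ratio()` (persistence under a change scenario relative to
the reference, averaged within the four consecutive budget quartiles of the
sweep — for 400 budgets, blocks of 100).

## 7. Degenerate inputs, tolerances, limitations

- Budgets of 0 yield empty solutions (maxPers objective 0; shortfall 1 per
  species); negative budgets are rejected.
- Cost layers must price every candidate cell-period; anything else is an
  error, not a silent 0.
- Feasibility/optimality tolerances: budget satisfied to 1e-9; objective
  comparisons in tests at 1e-9; branch-and-bound pruning margin 1e-12.
- The per-species mixed model requires at least two budget levels and one
  multi-level fixed factor; quartile subsets of very short sweeps can fail
  this requirement by construction.
- Known limitations: no functional (habitat-aware) dispersal, no
  within-period metapopulation dynamics, no land-release crediting over
  time, no acquisition-versus-management cost split, and no geographic
  projections — coordinates are planar km throughout.

## 8. A worked micro-example

```{r example}
# two cells a=0, b=1 over two periods, unit costs
cand <- tibble::tibble(species_id = "s", rank = 1:3,
                       cell_1 = c(0L, 0L, 1L), cell_2 = c(1L, 0L, 1L),
                       persistence = c(0.81, 0.72, 0.45))
cl <- tidyr::expand_grid(cell_id = 0:1, period = 1:2) |>
  dplyr::mutate(cost = 1)
# B = 4: the best corridor conflicts with both others; the pair wins
glance(solve_max_pers(cand, cl, budget = 4))
# B = 2: only one corridor is affordable
tidy(solve_max_pers(cand, cl, budget = 2))
```
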