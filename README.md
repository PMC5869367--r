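# cccplan

Scheduling conservation areas through time for species tracking a changing
climate, under a budget.

## The problem

As climate shifts, the places worth protecting for a species move. A static
reserve bought today may be useless in sixty years, while the land the
species will need then is still affordable now. `cccplan` implements a
quantitative framework for *climate-change corridors* (CCCs): time-ordered
sequences of grid cells, one per planning period, that a species is expected
to occupy as its climatic niche moves. The package selects portfolios of
such corridors under an explicit budget and quantifies how climate scenario,
dispersal ability, socioeconomic land-use conflict, planning design and
budget each limit what conservation can achieve.

It is aimed at spatial conservation planners and ecologists who want to run
scheduling experiments on gridded suitability projections, and at
methodologists who want a fully testable, synthetic-data-driven
reimplementation of the corridor-scheduling approach.

## The model

For a species *s*, a corridor *c* = (u₁, …, u_T) over periods 1…T has
persistence score

P_sc = pos(u₁,1) · pds(u₁,u₂) · pos(u₂,2) · ⋯ · pds(u_{T−1},u_T) · pos(u_T,T)

where pos(i,t) ∈ [0,1] is the species' climatic suitability in cell *i* at
period *t* and pds(i,j) = exp(−α·d(i,j)) is the dispersal success over the
centroid distance, calibrated so that success at the species' maximum
per-period dispersal distance D_max equals 5%, 10% or 15% (the α₁/α₂/α₃
curves), truncated to 0 beyond D_max. A non-dispersal variant allows only
staying in place.

Two exact selection models are provided:

- **maxPers** (single-species, SS): maximise the summed persistence of a set
  of *independent* corridors (no two sharing a cell in the same period),
  with the cost of the union of used (cell, period) units ≤ B.
- **minShortfall** (multi-species, MS): given per-species persistence
  targets T_s (typically the SS optima at the same budget), minimise
  Σ_s max(0, (T_s − achieved_s)/T_s) under the same constraints; cell-periods
  shared across species are paid once.

Candidate corridors are the exact top-K (default K = 2,000) per species,
enumerated by dynamic programming over the time-layered graph. A factorial
driver sweeps climate × dispersal × conflict layer × budget in both designs,
and a linear mixed model (`persistence ~ design + climate + dispersal +
conflict + (1 | budget)`) turns the results into per-factor effect sizes
Peff = PeffΔ / Peffm, with marginal/conditional R² reported.

## Worked example

A small synthetic study: two species with Gaussian niches on an 8 × 8 grid
of 10-km cells, four 30-year periods, three climate scenarios.

```r
library(cccplan)

species <- dplyr::bind_rows(
  species_spec("water_vole", c(25, 25), 15, 0.9, d_max = 20),
  species_spec("desman",     c(55, 55), 15, 0.8, d_max = 10))
study <- make_study(study_config(n_species = 2, nx = 8, ny = 8,
                                 footprint_fraction = 0),
                    seed = 1, species = species)

cand <- study_candidates(study, dispersal_levels = c(ndisp = NA, a1 = 0.05),
                         K = 8)
ss <- run_ss(cand, "uniform", budget_sequence(4, 4, 20))
ms <- run_ms(cand, ss_targets(ss), "uniform", budget_sequence(4, 4, 20))

dplyr::filter(ss, climate == "A1FI", dispersal == "a1",
              species_id == "water_vole")
#>   design climate dispersal conflict budget species_id persistence  cost
#> 1 SS     A1FI    a1        uniform       4 water_vole      0.0368     4
#> 2 SS     A1FI    a1        uniform       8 water_vole      0.0676     8
#> 3 SS     A1FI    a1        uniform      12 water_vole      0.0878    12
#> 4 SS     A1FI    a1        uniform      16 water_vole      0.106     16
#> 5 SS     A1FI    a1        uniform      20 water_vole      0.106     16
```

Persistence grows with budget and saturates once adding further corridors
stops paying (at B = 20 the optimum still uses 16 units). The MS-to-SS
ratio — the fraction of the dedicated-plan persistence a species keeps in
the joint plan — rises with budget as competition between species relaxes:

```r
r <- ms_ss_ratio(ss, ms)
dplyr::summarise(dplyr::group_by(r, budget),
                 mean_ratio = mean(ratio, na.rm = TRUE))
#>   budget mean_ratio
#> 1      4      0.5
#> 2      8      0.623
#> 3     12      0.616
#> 4     16      0.633
#> 5     20      0.662
```

The effects analysis fits the per-species mixed model and ranks factors:

```r
fit <- fit_effects_model(dplyr::bind_rows(
  dplyr::select(ss, design:species_id, persistence),
  dplyr::select(ms, design:species_id, persistence)), species = "water_vole")
glance(fit)
#>   species    budget_subset  n var_fixed var_budget var_residual  R2m  R2c
#> 1 water_vole all           60     0.197     0.0271       0.0248 0.791 0.900
effect_sizes(fit)
#>   factor    PeffFm  PeffFd    Peff
#> 1 climate    0.535 1.04    1.95
#> 2 design     0.535 0.166   0.310
#> 3 dispersal  0.535 0.000416 0.000776
```

Here climate dominates (this species' niche erodes heavily under the severe
scenario), planning design matters, and dispersal ability barely registers —
R²m < R²c says the budget random intercepts absorb real variance beyond the
fixed factors. `plot_budget_sweep()`, `plot_effect_sizes()` and
`plot_suitability()` visualise these objects.

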