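# Fixtures are built in code: small landscapes, edge sets and random
# micro-problems shared across test files.

# landscape with explicit suitability values; pos is a matrix n_cells x T
tiny_landscape <- function(pos, species_id = "s", d_max = 1e4,
                           nx = nrow(pos), cell_size = 10,
                           footprint = 0, costs = NULL) {
  n <- nrow(pos)
  n_T <- ncol(pos)
  cells <- make_grid(nx, ceiling(n / nx), cell_size, footprint)[seq_len(n), ]
  suit <- tidyr::expand_grid(cell_id = 0:(n - 1), period = seq_len(n_T)) |>
    dplyr::mutate(species_id = species_id,
                  pos = pos[cbind(cell_id + 1, period)])
  if (is.null(costs)) costs <- uniform_cost_layer(n, n_T)
  ccc_landscape(cells,
                tibble::tibble(species_id = species_id, d_max = d_max),
                suit, dplyr::mutate(costs, activity = "uniform"),
                periods = paste0("p", seq_len(n_T)))
}

uniform_cost_layer <- function(n, n_T) {
  tidyr::expand_grid(cell_id = 0:(n - 1), period = seq_len(n_T)) |>
    dplyr::mutate(cost = 1)
}

# complete edge set with pds 1 (every transition feasible)
full_edges <- function(n) {
  tidyr::expand_grid(from = 0:(n - 1), to = 0:(n - 1)) |>
    dplyr::mutate(pds = 1)
}

# random selection micro-problem: small candidate set over few cells
random_micro_problem <- function(seed, n_species = 1) {
  withr::local_seed(seed)
  n <- sample(3:6, 1)
  n_T <- sample(2:3, 1)
  m <- sample(4:12, 1)
  sp_ids <- paste0("sp", seq_len(n_species))
  cand <- purrr::map(seq_len(m), function(i) {
    cells <- sample(0:(n - 1), n_T, replace = TRUE)
    tibble::tibble(species_id = sample(sp_ids, 1), rank = i,
                   !!!stats::setNames(as.list(as.integer(cells)),
                                      paste0("cell_", seq_len(n_T))),
                   persistence = stats::runif(1, 0.05, 1))
  }) |> dplyr::bind_rows()
  # make sure every species keeps at least one candidate
  cand$species_id[seq_len(n_species)] <- sp_ids
  cost <- tidyr::expand_grid(cell_id = 0:(n - 1), period = seq_len(n_T)) |>
    dplyr::mutate(cost = round(stats::runif(dplyr::n(), 0.5, 3), 2))
  budget <- stats::runif(1, 1, 0.6 * sum(cost$cost))
  targets <- cand |>
    dplyr::group_by(species_id) |>
    dplyr::summarise(target = max(persistence) * stats::runif(1, 0.6, 1.5)) |>
    (\(d) stats::setNames(d$target, d$species_id))()
  list(candidates = cand, cost_layer = cost, budget = budget, targets = targets)
}

# synthetic long results table with known additive effects and random
# budget intercepts; returns the table and the generating parameters
synthetic_results <- function(seed, mu = 0.5,
                              design_eff = c(SS = 0.1, MS = -0.1),
                              climate_eff = c(NC = 0.05, B1 = 0, A1FI = -0.05),
                              n_budgets = 20, budget_sd = 0.1,
                              noise_sd = 0.02) {
  withr::local_seed(seed)
  budgets <- seq(4, by = 4, length.out = n_budgets)
  b_int <- stats::setNames(stats::rnorm(n_budgets, 0, budget_sd),
                           as.character(budgets))
  tab <- tidyr::expand_grid(
    design = names(design_eff), climate = names(climate_eff),
    dispersal = c("ndisp", "a1"), conflict = c("uniform", "total"),
    budget = budgets
  ) |>
    dplyr::mutate(
      species_id = "sim",
      persistence = mu + design_eff[design] + climate_eff[climate] +
        b_int[as.character(budget)] +
        stats::rnorm(dplyr::n(), 0, noise_sd)
    )
  list(results = tab, mu = mu, design_eff = design_eff,
       climate_eff = climate_eff, b_int = b_int,
       noise_sd = noise_sd, budget_sd = budget_sd)
}
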