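#' Budget sequence for the conflict sweep
#'
#' An arithmetic budget sequence; the default (start 4, step 4, stop 1600)
#' yields 400 budgets, the first being the minimum cost of a single
#' four-period corridor under the uniform cost layer.
#'
#' @param start First budget. @param step Increment (> 0). @param stop Last
#'   budget (included when aligned with the step).
#' @return Numeric vector of budgets.
#' @examples
#' length(budget_sequence())  # 400
#' @export
budget_sequence <- function(start = 4, step = 4, stop = 1600) {
  if (step <= 0) stop("step must be > 0", call. = FALSE)
  if (start > stop) stop("start must not exceed stop", call. = FALSE)
  seq(start, stop, by = step)
}

#' Build the factorial run schedule
#'
#' Single-species (SS) planning schedules one persistence-maximisation run
#' per (species, climate, dispersal, conflict, budget) combination;
#' multi-species (MS) planning schedules one shortfall-minimisation run per
#' (climate, dispersal, conflict, budget), each covering all species.
#'
#' @param species,climates,dispersals,conflicts Character vectors of factor
#'   levels. @param budgets Numeric budgets (strictly increasing).
#' @param design `"SS"` or `"MS"`.
#' @return A tibble with one row per scheduled run; `nrow()` is the run count.
#' @examples
#' nrow(build_design(paste0("sp", 1:10), c("NC", "B1", "A1FI"),
#'                   c("ndisp", "a1", "a2", "a3"),
#'                   c("uniform", "agriculture", "pasture", "forestry",
#'                     "urban", "total"),
#'                   budget_sequence(), design = "SS"))  # 288000
#' @export
build_design <- function(species, climates, dispersals, conflicts, budgets,
                         design = c("SS", "MS")) {
  design <- match.arg(design)
  stopifnot(length(species) > 0, length(climates) > 0, length(dispersals) > 0,
            length(conflicts) > 0, length(budgets) > 0)
  if (is.unsorted(budgets, strictly = TRUE)) {
    stop("budgets must be strictly increasing", call. = FALSE)
  }
  base <- list(climate = climates, dispersal = dispersals,
               conflict = conflicts, budget = budgets)
  if (design == "SS") base <- c(list(species = species), base)
  out <- tidyr::expand_grid(!!!base)
  dplyr::mutate(out, design = design, .before = 1)
}

#' Standard dispersal levels
#'
#' Non-dispersal plus the three calibrated curves with 5%, 10% and 15%
#' success at `d_max`.
#'
#' @return Named numeric vector (`NA` marks non-dispersal) usable as the
#'   `dispersal_levels` argument of [study_candidates()].
#' @export
dispersal_levels <- function() {
  c(ndisp = NA_real_, a1 = 0.05, a2 = 0.10, a3 = 0.15)
}

#' Enumerate candidate corridors across an experiment grid
#'
#' Applies the footprint filter, then enumerates the top-K corridors per
#' (climate scenario, dispersal level, species). Candidate sets depend only
#' on suitability and dispersal, not on budgets or cost layers, so they are
#' computed once and reused across the whole sweep.
#'
#' @param study Named list of `ccc_landscape`, one per climate scenario
#'   (e.g. from [make_study()]).
#' @param dispersal_levels Named numeric vector as from [dispersal_levels()]:
#'   values are the kernel success probability at `d_max`, `NA` for
#'   non-dispersal.
#' @param K Candidates kept per species.
#' @param footprint_threshold Passed to [apply_footprint_filter()].
#' @return A tibble of candidates with leading columns `climate`,
#'   `dispersal`; carries the filtered landscapes as attribute `"landscapes"`.
#' @export
study_candidates <- function(study, dispersal_levels = cccplan::dispersal_levels(),
                             K = 12, footprint_threshold = 60) {
  stopifnot(length(study) >= 1, !is.null(names(study)))
  filtered <- purrr::map(study, apply_footprint_filter,
                         threshold = footprint_threshold)
  edge_cache <- new.env(parent = emptyenv())
  out <- purrr::imap(filtered, function(land, climate) {
    purrr::imap(dispersal_levels, function(p_at_dmax, dlev) {
      purrr::map(seq_len(nrow(land$species)), function(i) {
        sp <- land$species[i, ]
        key <- paste(dlev, format(sp$d_max, digits = 12), sep = "|")
        if (is.null(edge_cache[[key]])) {
          kernel <- if (is.na(p_at_dmax)) {
            nondispersal_kernel()
          } else {
            calibrate_kernel(sp$d_max, p_at_dmax)
          }
          edge_cache[[key]] <- build_pds_edges(land$cells, kernel)
        }
        cand <- suppressWarnings(
          enumerate_candidates(land, sp$species_id, edge_cache[[key]], K)
        )
        if (nrow(cand)) {
          dplyr::mutate(cand, climate = climate, dispersal = dlev, .before = 1)
        } else {
          NULL
        }
      }) |> dplyr::bind_rows()
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  attr(out, "landscapes") <- filtered
  out
}

cost_layer_of <- function(landscape, conflict) {
  cl <- landscape$costs[landscape$costs$activity == conflict,
                        c("cell_id", "period", "cost")]
  if (nrow(cl) == 0) {
    stop("no cost layer named '", conflict, "' in the landscape", call. = FALSE)
  }
  cl
}

#' Run the single-species (SS) sweep
#'
#' Executes one exact persistence-maximisation run per (species, climate,
#' dispersal, conflict, budget) combination. The optimised per-species
#' persistence values are the targets later fed to the multi-species model.
#' Species with no positive-persistence corridor under a setting are recorded
#' with persistence 0.
#'
#' @param candidates Output of [study_candidates()].
#' @param conflicts Cost-layer names to sweep (must exist in the landscapes).
#' @param budgets Numeric vector of budgets.
#' @return Results tibble with one row per (run, species): columns `design`,
#'   `climate`, `dispersal`, `conflict`, `budget`, `species_id`,
#'   `persistence`, `cost`, `n_selected`.
#' @export
run_ss <- function(candidates, conflicts = c("uniform", "total"),
                   budgets = budget_sequence(4, 4, 40)) {
  landscapes <- attr(candidates, "landscapes")
  stopifnot(!is.null(landscapes))
  grid <- tidyr::expand_grid(
    climate = unique(candidates$climate),
    dispersal = unique(candidates$dispersal),
    conflict = conflicts
  )
  all_species <- sort(unique(unlist(purrr::map(landscapes, ~ .x$species$species_id))))
  purrr::pmap(grid, function(climate, dispersal, conflict) {
    land <- landscapes[[climate]]
    cl <- cost_layer_of(land, conflict)
    purrr::map(all_species, function(sid) {
      cand <- candidates[candidates$climate == climate &
                           candidates$dispersal == dispersal &
                           candidates$species_id == sid, ]
      cand <- dplyr::select(cand, -"climate", -"dispersal")
      purrr::map(budgets, function(B) {
        if (nrow(cand) == 0) {
          return(tibble::tibble(design = "SS", climate = climate,
                                dispersal = dispersal, conflict = conflict,
                                budget = B, species_id = sid, persistence = 0,
                                cost = 0, n_selected = 0L))
        }
        sol <- solve_max_pers(cand, cl, B)
        tibble::tibble(design = "SS", climate = climate, dispersal = dispersal,
                       conflict = conflict, budget = B, species_id = sid,
                       persistence = sol$objective, cost = sol$total_cost,
                       n_selected = nrow(sol$selected))
      }) |> dplyr::bind_rows()
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
}

#' Extract multi-species targets from SS results
#'
#' @param results_ss Tibble from [run_ss()].
#' @return Tibble `climate`, `dispersal`, `conflict`, `budget`, `species_id`,
#'   `target`.
#' @export
ss_targets <- function(results_ss) {
  dplyr::select(results_ss, "climate", "dispersal", "conflict", "budget",
                "species_id", target = "persistence")
}

#' Run the multi-species (MS) sweep
#'
#' Executes one exact shortfall-minimisation run per (climate, dispersal,
#' conflict, budget) combination, covering all species, using the SS optima
#' as persistence targets. Species whose target is 0 (nothing achievable even
#' in a dedicated plan) are excluded from the objective and reported with
#' shortfall `NA`.
#'
#' @param candidates Output of [study_candidates()].
#' @param targets Tibble from [ss_targets()].
#' @inheritParams run_ss
#' @return Results tibble with one row per (run, species): columns as in
#'   [run_ss()] plus `target` and `shortfall`.
#' @export
run_ms <- function(candidates, targets, conflicts = c("uniform", "total"),
                   budgets = budget_sequence(4, 4, 40)) {
  landscapes <- attr(candidates, "landscapes")
  stopifnot(!is.null(landscapes))
  grid <- tidyr::expand_grid(
    climate = unique(candidates$climate),
    dispersal = unique(candidates$dispersal),
    conflict = conflicts
  )
  all_species <- sort(unique(unlist(purrr::map(landscapes, ~ .x$species$species_id))))
  purrr::pmap(grid, function(climate, dispersal, conflict) {
    land <- landscapes[[climate]]
    cl <- cost_layer_of(land, conflict)
    cand <- candidates[candidates$climate == climate &
                         candidates$dispersal == dispersal, ]
    cand <- dplyr::select(cand, -"climate", -"dispersal")
    purrr::map(budgets, function(B) {
      tg <- targets[targets$climate == climate &
                      targets$dispersal == dispersal &
                      targets$conflict == conflict &
                      targets$budget == B, ]
      if (nrow(tg) == 0) {
        stop(sprintf("no targets for run (%s, %s, %s, B = %s)",
                     climate, dispersal, conflict, format(B)), call. = FALSE)
      }
      tv <- stats::setNames(tg$target, tg$species_id)
      active <- names(tv)[tv > 0]
      cand_run <- cand[cand$species_id %in% active, ]
      sol <- solve_min_shortfall(cand_run, cl, B, tv[active])
      ap <- achieved_persistence(sol)
      tibble::tibble(
        design = "MS", climate = climate, dispersal = dispersal,
        conflict = conflict, budget = B, species_id = all_species,
        persistence = ifelse(all_species %in% ap$species_id,
                             ap$achieved[match(all_species, ap$species_id)], 0),
        target = unname(tv[all_species]),
        shortfall = ifelse(all_species %in% ap$species_id,
                           ap$shortfall[match(all_species, ap$species_id)],
                           NA_real_),
        cost = sol$total_cost,
        n_selected = nrow(sol$selected)
      )
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
}

#' Run the full SS -> MS factorial experiment
#'
#' Convenience driver: enumerates candidates, runs the SS sweep, extracts
#' targets, runs the MS sweep, and returns everything including a combined
#' long results table ready for the effects analysis.
#'
#' @param study Named list of `ccc_landscape` per climate scenario.
#' @inheritParams study_candidates
#' @inheritParams run_ss
#' @return List with elements `ss`, `ms`, `targets`, `results` (rows of both
#'   designs; MS-only columns dropped) and `candidates`.
#' @export
run_experiment <- function(study, dispersal_levels = cccplan::dispersal_levels(),
                           conflicts = c("uniform", "total"),
                           budgets = budget_sequence(4, 4, 40), K = 12,
                           footprint_threshold = 60) {
  cand <- study_candidates(study, dispersal_levels, K, footprint_threshold)
  ss <- run_ss(cand, conflicts, budgets)
  tg <- ss_targets(ss)
  ms <- run_ms(cand, tg, conflicts, budgets)
  combined <- dplyr::bind_rows(
    dplyr::select(ss, "design", "climate", "dispersal", "conflict", "budget",
                  "species_id", "persistence"),
    dplyr::select(ms, "design", "climate", "dispersal", "conflict", "budget",
                  "species_id", "persistence")
  )
  list(ss = ss, ms = ms, targets = tg, results = combined, candidates = cand)
}
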