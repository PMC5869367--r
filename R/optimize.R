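#' Select corridors maximising a species' persistence under a budget
#'
#' The single-species selection model: choose a set of pairwise independent
#' candidate corridors (no two sharing a cell in the same period) whose
#' summed persistence is maximal, subject to the cost of the union of used
#' (cell, period) units not exceeding the budget. Solved exactly by
#' branch-and-bound; the returned solution is provably optimal.
#'
#' @param candidates Candidate tibble from [enumerate_candidates()] (one
#'   species).
#' @param cost_layer Cost tibble `cell_id`, `period`, `cost` for the chosen
#'   activity (e.g. `dplyr::filter(landscape$costs, activity == "uniform")`).
#' @param budget Available budget B (>= 0); with B = 0 the empty solution is
#'   returned.
#' @param node_limit Safety cap on branch-and-bound nodes.
#' @return A `ccc_solution` object; see [tidy.ccc_solution()] and
#'   [glance.ccc_solution()].
#' @export
solve_max_pers <- function(candidates, cost_layer, budget, node_limit = 1e7) {
  if (dplyr::n_distinct(candidates$species_id) > 1) {
    stop("solve_max_pers expects candidates of a single species", call. = FALSE)
  }
  solve_ccc(candidates, cost_layer, budget, mode = "maxPers",
            targets = NULL, node_limit = node_limit)
}

#' Select corridors minimising summed proportional shortfalls to targets
#'
#' The multi-species selection model: each species has a persistence target
#' (typically its dedicated single-species optimum at the same budget); the
#' model minimises the sum across species of `max(0, (target - achieved) /
#' target)` under within-species independence and the shared budget. A
#' (cell, period) unit used by corridors of several species is paid for once.
#' Exceeding a target earns no credit. Solved exactly by branch-and-bound.
#'
#' @param candidates Candidate tibble covering all species.
#' @param cost_layer Cost tibble `cell_id`, `period`, `cost`.
#' @param budget Available budget B (>= 0).
#' @param targets Named numeric vector (or tibble `species_id`, `target`) of
#'   strictly positive persistence targets, one per species present.
#' @param node_limit Safety cap on branch-and-bound nodes.
#' @return A `ccc_solution` object.
#' @export
solve_min_shortfall <- function(candidates, cost_layer, budget, targets,
                                node_limit = 1e7) {
  solve_ccc(candidates, cost_layer, budget, mode = "minShortfall",
            targets = targets, node_limit = node_limit)
}

as_target_vector <- function(targets, species_ids) {
  if (is.data.frame(targets)) {
    targets <- stats::setNames(targets$target, targets$species_id)
  }
  missing <- setdiff(species_ids, names(targets))
  if (length(missing)) {
    stop("missing targets for species: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  tv <- targets[species_ids]
  if (any(tv <= 0 | is.na(tv))) {
    stop("targets must be strictly positive", call. = FALSE)
  }
  tv
}

solve_ccc <- function(candidates, cost_layer, budget, mode, targets,
                      node_limit = 1e7) {
  stopifnot(budget >= 0)
  n_T <- ncol(candidate_cells(candidates))
  species_ids <- sort(unique(candidates$species_id))
  m <- nrow(candidates)

  if (mode == "minShortfall") {
    tv <- as_target_vector(targets, species_ids)
  } else {
    tv <- numeric(0)
  }

  n <- max(c(cost_layer$cell_id, if (m) candidate_cells(candidates))) + 1L
  w <- rep(NA_real_, n * n_T)
  w[(cost_layer$period - 1L) * n + cost_layer$cell_id + 1L] <- cost_layer$cost

  if (m == 0) {
    sol <- list(selected = integer(0), value = 0, cost = 0,
                achieved = rep(0, length(species_ids)), nodes = 0)
  } else {
    cm <- candidate_cells(candidates)
    ct <- sweep(matrix(0L, m, n_T), 2, (seq_len(n_T) - 1L) * n, `+`) + cm
    if (anyNA(w[as.vector(ct) + 1L])) {
      stop("cost layer does not cost every candidate (cell, period)",
           call. = FALSE)
    }
    w0 <- w
    w0[is.na(w0)] <- 0
    sp <- match(candidates$species_id, species_ids) - 1L
    sol <- ccc_solve_cpp(ct, sp, candidates$persistence, w0, budget,
                         ifelse(mode == "maxPers", 0L, 1L),
                         as.numeric(tv), node_limit)
  }

  achieved <- stats::setNames(sol$achieved, species_ids)
  if (mode == "minShortfall") {
    shortfalls <- pmax(0, (tv - achieved) / tv)
    objective <- sum(shortfalls)
  } else {
    shortfalls <- stats::setNames(rep(NA_real_, length(species_ids)), species_ids)
    objective <- sol$value
  }
  structure(
    list(
      mode = mode,
      selected = candidates[sol$selected + 1L, , drop = FALSE],
      achieved = achieved,
      shortfalls = shortfalls,
      targets = if (length(tv)) tv else NULL,
      total_cost = sol$cost,
      budget = budget,
      objective = objective,
      nodes = sol$nodes
    ),
    class = "ccc_solution"
  )
}

#' @export
print.ccc_solution <- function(x, ...) {
  cat("<ccc_solution> ", x$mode, ": ", nrow(x$selected), " corridors, cost ",
      format(x$total_cost), " / budget ", format(x$budget),
      ", objective ", format(x$objective), "\n", sep = "")
  invisible(x)
}

#' Tidy a corridor-selection solution
#'
#' @param x A `ccc_solution`.
#' @param ... Unused.
#' @return `tidy()` returns the selected corridors as a tibble;
#'   `glance()` a one-row summary (objective, total cost, budget, per-species
#'   achieved persistence is in `tidy()`'s `persistence` column).
#' @export
tidy.ccc_solution <- function(x, ...) {
  x$selected
}

#' @rdname tidy.ccc_solution
#' @export
glance.ccc_solution <- function(x, ...) {
  tibble::tibble(
    mode = x$mode,
    n_selected = nrow(x$selected),
    objective = x$objective,
    total_cost = x$total_cost,
    budget = x$budget,
    total_shortfall = if (x$mode == "minShortfall") sum(x$shortfalls) else NA_real_
  )
}

#' Per-species achieved persistence of a solution
#' @param solution A `ccc_solution`.
#' @return Tibble `species_id`, `achieved` (plus `target`, `shortfall` for
#'   multi-species solutions).
#' @export
achieved_persistence <- function(solution) {
  out <- tibble::tibble(species_id = names(solution$achieved),
                        achieved = unname(solution$achieved))
  if (solution$mode == "minShortfall") {
    out$target <- unname(solution$targets[out$species_id])
    out$shortfall <- unname(solution$shortfalls[out$species_id])
  }
  out
}

#' Exhaustive selection oracle
#'
#' Enumerates every subset of the candidate set, discards those violating
#' within-species independence or the union-cost budget, and returns the best
#' under the same objective as [solve_max_pers()] / [solve_min_shortfall()].
#' Among equal-objective optima the lexicographically smallest candidate
#' index set wins. Refuses more than 20 candidates.
#'
#' @inheritParams solve_min_shortfall
#' @param mode `"maxPers"` or `"minShortfall"`.
#' @return A `ccc_solution`.
#' @export
brute_force_solve <- function(candidates, cost_layer, budget,
                              mode = c("maxPers", "minShortfall"),
                              targets = NULL) {
  mode <- match.arg(mode)
  m <- nrow(candidates)
  if (m > 20) stop("instance too large for the brute-force oracle", call. = FALSE)
  species_ids <- sort(unique(candidates$species_id))
  tv <- if (mode == "minShortfall") as_target_vector(targets, species_ids)
  n_T <- if (m) ncol(candidate_cells(candidates)) else max(cost_layer$period)
  n <- max(c(cost_layer$cell_id, if (m) candidate_cells(candidates))) + 1L
  w <- rep(NA_real_, n * n_T)
  w[(cost_layer$period - 1L) * n + cost_layer$cell_id + 1L] <- cost_layer$cost
  ct_list <- if (m) {
    cm <- candidate_cells(candidates)
    lapply(seq_len(m), function(c) (seq_len(n_T) - 1L) * n + cm[c, ] + 1L)
  } else list()

  best <- NULL
  eval_subset <- function(idx) {
    # independence within species
    for (s in species_ids) {
      ii <- idx[candidates$species_id[idx] == s]
      cts <- unlist(ct_list[ii])
      if (anyDuplicated(cts)) return(NULL)
    }
    used <- unique(unlist(ct_list[idx]))
    cost <- if (length(used)) sum(w[used]) else 0
    if (is.na(cost) || cost > budget + 1e-9) return(NULL)
    achieved <- vapply(species_ids, function(s) {
      sum(candidates$persistence[idx[candidates$species_id[idx] == s]])
    }, numeric(1))
    if (mode == "maxPers") {
      list(obj = sum(achieved), achieved = achieved, cost = cost, better_high = TRUE)
    } else {
      sf <- pmax(0, (tv - achieved) / tv)
      list(obj = sum(sf), achieved = achieved, cost = cost, better_high = FALSE)
    }
  }

  for (mask in 0:(2^m - 1)) {
    idx <- which(bitwAnd(mask, bitwShiftL(1, seq_len(m) - 1)) > 0)
    r <- eval_subset(idx)
    if (is.null(r)) next
    if (is.null(best)) {
      best <- c(r, list(idx = idx))
    } else {
      d <- if (r$better_high) r$obj - best$obj else best$obj - r$obj
      if (d > 1e-12) {
        best <- c(r, list(idx = idx))
      } else if (abs(d) <= 1e-12 && lex_less(r_idx = idx, best$idx)) {
        best <- c(r, list(idx = idx))
      }
    }
  }
  achieved <- stats::setNames(best$achieved, species_ids)
  shortfalls <- if (mode == "minShortfall") {
    pmax(0, (tv - achieved) / tv)
  } else {
    stats::setNames(rep(NA_real_, length(species_ids)), species_ids)
  }
  structure(
    list(mode = mode,
         selected = candidates[best$idx, , drop = FALSE],
         achieved = achieved, shortfalls = shortfalls,
         targets = if (mode == "minShortfall") tv else NULL,
         total_cost = best$cost, budget = budget,
         objective = best$obj, nodes = NA_real_),
    class = "ccc_solution"
  )
}

# lexicographic order on index sets (shorter prefix-equal set first)
lex_less <- function(r_idx, b_idx) {
  k <- min(length(r_idx), length(b_idx))
  if (k > 0) {
    for (i in seq_len(k)) {
      if (r_idx[i] != b_idx[i]) return(r_idx[i] < b_idx[i])
    }
  }
  length(r_idx) < length(b_idx)
}
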