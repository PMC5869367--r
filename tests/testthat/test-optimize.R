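# three candidates over cells {a = 0, b = 1}, T = 2:
# c1 = (a, b) P 0.81, c2 = (a, a) P 0.72, c3 = (b, b) P 0.45; unit costs
worked_candidates <- function() {
  tibble::tibble(
    species_id = "s", rank = 1:3,
    cell_1 = c(0L, 0L, 1L), cell_2 = c(1L, 0L, 1L),
    persistence = c(0.81, 0.72, 0.45)
  )
}

test_that("maxPers resolves the worked independence/budget example", {
  cand <- worked_candidates()
  cl <- uniform_cost_layer(2, 2)
  # B = 4: c1 conflicts with both c2 (a@t1) and c3 (b@t2) -> {c2, c3}
  s4 <- solve_max_pers(cand, cl, 4)
  expect_equal(s4$objective, 1.17)
  expect_setequal(s4$selected$rank, c(2L, 3L))
  expect_equal(s4$total_cost, 4)
  # B = 2: only one corridor affordable -> the best one
  s2 <- solve_max_pers(cand, cl, 2)
  expect_equal(s2$objective, 0.81)
  expect_identical(s2$selected$rank, 1L)
  # B = 0: empty solution
  s0 <- solve_max_pers(cand, cl, 0)
  expect_identical(nrow(s0$selected), 0L)
  expect_equal(s0$objective, 0)
})

test_that("minShortfall meets feasible targets and degrades gracefully", {
  # two species with disjoint candidates and ample budget: zero shortfall
  cand <- tibble::tibble(
    species_id = c("s1", "s2"), rank = c(1L, 1L),
    cell_1 = c(0L, 2L), cell_2 = c(1L, 3L),
    persistence = c(0.81, 0.45)
  )
  cl <- uniform_cost_layer(4, 2)
  tg <- c(s1 = 0.81, s2 = 0.45)
  ample <- solve_min_shortfall(cand, cl, 100, tg)
  expect_equal(ample$objective, 0)
  expect_equal(unname(ample$achieved), c(0.81, 0.45))
  # B = 0: shortfall 1 per species
  zero <- solve_min_shortfall(cand, cl, 0, tg)
  expect_equal(zero$objective, 2)
  expect_equal(unname(zero$shortfalls), c(1, 1))
  # B = 2 with 2-unit corridors: one species fully met, the other at 1
  tight <- solve_min_shortfall(cand, cl, 2, tg)
  expect_equal(tight$objective, 1)
})

test_that("targets must be strictly positive and complete", {
  cand <- worked_candidates()
  cl <- uniform_cost_layer(2, 2)
  expect_error(solve_min_shortfall(cand, cl, 4, c(s = 0)), "positive")
  expect_error(solve_min_shortfall(cand, cl, 4, c(other = 1)), "missing targets")
})

test_that("branch-and-bound matches the exhaustive oracle on micro-instances", {
  # single-species maxPers
  for (seed in 1:60) {
    p <- random_micro_problem(seed, n_species = 1)
    bb <- solve_max_pers(p$candidates, p$cost_layer, p$budget)
    or <- brute_force_solve(p$candidates, p$cost_layer, p$budget, "maxPers")
    expect_equal(bb$objective, or$objective, tolerance = 1e-9)
    expect_lte(bb$total_cost, p$budget + 1e-9)
  }
  # multi-species minShortfall
  for (seed in 101:160) {
    p <- random_micro_problem(seed, n_species = 2 + seed %% 2)
    bb <- solve_min_shortfall(p$candidates, p$cost_layer, p$budget, p$targets)
    or <- brute_force_solve(p$candidates, p$cost_layer, p$budget,
                            "minShortfall", p$targets)
    expect_equal(bb$objective, or$objective, tolerance = 1e-9)
    expect_lte(bb$total_cost, p$budget + 1e-9)
  }
})

test_that("selected corridors are independent and correctly costed", {
  checked <- 0
  for (seed in 11:30) {
    p <- random_micro_problem(seed, n_species = 2)
    sol <- solve_min_shortfall(p$candidates, p$cost_layer, p$budget, p$targets)
    sel <- sol$selected
    if (nrow(sel) == 0) next
    checked <- checked + 1
    n_T <- sum(grepl("^cell_", names(sel)))
    # within-species independence: no (cell, period) reused
    for (s in unique(sel$species_id)) {
      ss <- sel[sel$species_id == s, ]
      ct <- unlist(lapply(seq_len(n_T), function(t)
        paste(ss[[paste0("cell_", t)]], t)))
      expect_identical(anyDuplicated(ct), 0L)
    }
    # union cost recomputed from the layer
    ct_all <- unique(unlist(lapply(seq_len(n_T), function(t)
      paste(sel[[paste0("cell_", t)]], t))))
    w <- stats::setNames(p$cost_layer$cost,
                         paste(p$cost_layer$cell_id, p$cost_layer$period))
    expect_equal(sol$total_cost, sum(w[ct_all]) + 0)
    # achieved persistence recomputed from the selected corridors
    ach <- tapply(sel$persistence, sel$species_id, sum)
    expect_equal(unname(sol$achieved[names(ach)]), as.vector(ach),
                 tolerance = 1e-9)
  }
  expect_gte(checked, 5)
})

test_that("optimal objectives are monotone along a budget sweep", {
  p <- random_micro_problem(42, n_species = 2)
  budgets <- seq(0, 1.2 * sum(p$cost_layer$cost), length.out = 12)
  mp <- purrr::map_dbl(budgets, function(B) {
    cand1 <- p$candidates[p$candidates$species_id == "sp1", ]
    solve_max_pers(cand1, p$cost_layer, B)$objective
  })
  expect_true(all(diff(mp) >= -1e-9))
  ms <- purrr::map_dbl(budgets, function(B) {
    solve_min_shortfall(p$candidates, p$cost_layer, B, p$targets)$objective
  })
  expect_true(all(diff(ms) <= 1e-9))
})

test_that("single-species shortfall is consistent with the dedicated optimum", {
  p <- random_micro_problem(77, n_species = 1)
  opt <- solve_max_pers(p$candidates, p$cost_layer, p$budget)$objective
  expect_gt(opt, 0)
  sol <- solve_min_shortfall(p$candidates, p$cost_layer, p$budget,
                             c(sp1 = opt))
  expect_equal(sol$objective, 0, tolerance = 1e-9)
  expect_equal(unname(sol$achieved), opt, tolerance = 1e-9)
})

test_that("the oracle handles trivial candidate sets", {
  cl <- uniform_cost_layer(2, 2)
  empty <- worked_candidates()[0, ]
  s <- brute_force_solve(empty, cl, 10, "maxPers")
  expect_identical(nrow(s$selected), 0L)
  one <- worked_candidates()[1, ]
  s1 <- brute_force_solve(one, cl, 10, "maxPers")
  expect_identical(nrow(s1$selected), 1L)
  expect_error(
    brute_force_solve(dplyr::bind_rows(replicate(8, worked_candidates(),
                                                 simplify = FALSE)),
                      cl, 10, "maxPers"),
    "too large"
  )
})
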