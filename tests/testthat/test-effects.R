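test_that("known additive effects are recovered within 3 standard errors", {
  sim <- synthetic_results(seed = 31)
  fit <- fit_effects_model(sim$results, species = "sim")
  co <- tidy(fit)
  # treatment-contrast truths relative to the alphabetically first level
  truth <- c(
    designSS = unname(sim$design_eff["SS"] - sim$design_eff["MS"]),
    climateB1 = unname(sim$climate_eff["B1"] - sim$climate_eff["A1FI"]),
    climateNC = unname(sim$climate_eff["NC"] - sim$climate_eff["A1FI"]),
    dispersalndisp = 0,
    conflictuniform = 0
  )
  for (term in names(truth)) {
    row <- co[co$term == term, ]
    expect_identical(nrow(row), 1L)
    expect_lt(abs(row$estimate - truth[[term]]), 3 * row$std.error)
  }
})

test_that("variance partition hits the limiting cases", {
  # pure fixed effects, (almost) no noise, no budget variance
  pure <- synthetic_results(seed = 5, budget_sd = 0, noise_sd = 1e-6)
  f1 <- suppressWarnings(fit_effects_model(pure$results, species = "sim"))
  g1 <- glance(f1)
  expect_equal(g1$R2m, 1, tolerance = 1e-3)
  expect_equal(g1$R2c, 1, tolerance = 1e-3)
  # response independent of every factor
  null <- synthetic_results(seed = 6, design_eff = c(SS = 0, MS = 0),
                            climate_eff = c(NC = 0, B1 = 0, A1FI = 0),
                            budget_sd = 0, noise_sd = 0.1)
  f0 <- suppressWarnings(fit_effects_model(null$results, species = "sim"))
  expect_lt(glance(f0)$R2m, 0.05)
  # dominant budget variance: marginal far below conditional
  rnd <- synthetic_results(seed = 7, design_eff = c(SS = 0.01, MS = -0.01),
                           climate_eff = c(NC = 0, B1 = 0, A1FI = 0),
                           budget_sd = 0.5, noise_sd = 0.01)
  gr <- glance(suppressWarnings(fit_effects_model(rnd$results, species = "sim")))
  expect_lt(gr$R2m, 0.2)
  expect_gt(gr$R2c, 0.9)
})

test_that("R2m <= R2c and both lie in [0, 1] across seeds and subsets", {
  for (seed in 1:5) {
    sim <- synthetic_results(seed = seed, budget_sd = 0.05 * seed)
    for (subset in list("all", 1, 4)) {
      g <- glance(suppressWarnings(
        fit_effects_model(sim$results, species = "sim", budget_subset = subset)))
      expect_gte(g$R2m, 0)
      expect_lte(g$R2m, g$R2c + 1e-12)
      expect_lte(g$R2c, 1)
    }
  }
})

test_that("degenerate designs are rejected", {
  sim <- synthetic_results(seed = 8)
  one_budget <- sim$results[sim$results$budget == 4, ]
  expect_error(fit_effects_model(one_budget, species = "sim"), "budget")
  flat <- dplyr::mutate(sim$results, design = "SS", climate = "NC",
                        dispersal = "a1", conflict = "uniform")
  expect_error(fit_effects_model(flat, species = "sim"), "fixed factor")
})

test_that("effect size reproduces the direct two-level formula", {
  # construct data whose balanced design-level estimates are 0.4 and 0.6
  sim <- synthetic_results(seed = 9, mu = 0.5,
                           design_eff = c(SS = 0.1, MS = -0.1),
                           climate_eff = c(NC = 0, B1 = 0, A1FI = 0),
                           budget_sd = 0.02, noise_sd = 1e-4)
  fit <- suppressWarnings(fit_effects_model(sim$results, species = "sim"))
  e <- effect_size(fit, "design")
  expect_equal(sort(e$estimate), c(0.4, 0.6), tolerance = 1e-2)
  expect_equal(attr(e, "PeffFm"), 0.5, tolerance = 1e-2)
  expect_equal(attr(e, "PeffFd"), 0.2, tolerance = 1e-2)
  expect_equal(attr(e, "Peff"), 0.4, tolerance = 1e-2)
  # a factor with no effect has Peff ~ 0 and never exactly negative
  e0 <- effect_size(fit, "climate")
  expect_lt(attr(e0, "Peff"), 0.01)
  expect_gte(attr(e0, "Peff"), 0)
  expect_error(effect_size(fit, "budget"), "not a fitted fixed factor")
})

test_that("balanced marginal estimates agree with emmeans", {
  skip_if_not_installed("emmeans")
  sim <- synthetic_results(seed = 10)
  fit <- fit_effects_model(sim$results, species = "sim")
  e <- effect_size(fit, "climate")
  em <- suppressMessages(
    as.data.frame(emmeans::emmeans(fit$model, "climate", weights = "equal"))
  )
  expect_equal(e$estimate[match(em$climate, e$level)], em$emmean,
               tolerance = 1e-8)
})

test_that("Peff is invariant to rescaling persistence", {
  sim <- synthetic_results(seed = 12)
  f1 <- fit_effects_model(sim$results, species = "sim")
  scaled <- dplyr::mutate(sim$results, persistence = persistence * 37)
  f2 <- fit_effects_model(scaled, species = "sim")
  expect_equal(attr(effect_size(f1, "design"), "Peff"),
               attr(effect_size(f2, "design"), "Peff"), tolerance = 1e-8)
})

test_that("a dominant design gap ranks design first among effect sizes", {
  sim <- synthetic_results(seed = 13,
                           design_eff = c(SS = 0.2, MS = -0.2),
                           climate_eff = c(NC = 0.02, B1 = 0, A1FI = -0.02))
  fit <- fit_effects_model(sim$results, species = "sim")
  es <- effect_sizes(fit)
  expect_identical(es$factor[1], "design")
})

test_that("the joint-to-dedicated persistence ratio behaves at the extremes", {
  ss <- tibble::tibble(climate = "NC", dispersal = "a1", conflict = "uniform",
                       budget = c(4, 8), species_id = "s",
                       persistence = c(0.5, 0))
  ms <- dplyr::mutate(ss, persistence = c(0.5, 0))
  r <- ms_ss_ratio(ss, ms)
  expect_equal(r$ratio, c(1, NA_real_))
  ms0 <- dplyr::mutate(ss, persistence = 0)
  expect_equal(ms_ss_ratio(ss, ms0)$ratio, c(0, NA_real_))
  # unmatched settings are a join error
  expect_error(ms_ss_ratio(ss[1, ], ms), "no SS counterpart")
})

test_that("competing species show a ratio below one, matching the oracle", {
  cand <- tibble::tibble(
    species_id = c("s1", "s2"), rank = 1L,
    cell_1 = c(0L, 1L), cell_2 = c(0L, 1L),
    persistence = c(0.8, 0.6)
  )
  cl <- uniform_cost_layer(2, 2)
  tg <- c(s1 = 0.8, s2 = 0.6)
  sol <- solve_min_shortfall(cand, cl, 2, tg)
  oracle <- brute_force_solve(cand, cl, 2, "minShortfall", tg)
  expect_equal(sol$objective, oracle$objective, tolerance = 1e-12)
  ratios <- sol$achieved / tg
  expect_true(any(ratios < 1))
  expect_true(all(ratios <= 1 + 1e-9))
})

test_that("climate effect ratios recover the closed-form erosion product", {
  # stationary niche, non-dispersal, no noise: the corridor is one fixed cell,
  # so the ratio of persistence under erosion e over T periods to no-change is
  # prod_t (1 - e)^(t - 1)
  e <- 0.16
  n_T <- 4
  cfg <- study_config(n_species = 1, nx = 6, ny = 6, footprint_fraction = 0,
                      noise_sd = 0, baseline_cutoff = 0,
                      scenarios = dplyr::bind_rows(
                        scenario_spec("NC", 0, 0),
                        scenario_spec("A1FI", 0, e)))
  sp <- species_spec("s", c(30, 30), 20, 0.9, d_max = 10)
  st <- make_study(cfg, seed = 2, species = sp)
  cand <- study_candidates(st, dispersal_levels = c(ndisp = NA), K = 1)
  budgets <- budget_sequence(4, 4, 16)
  ss <- run_ss(cand, "uniform", budgets)
  cer <- climate_effect_ratio(
    dplyr::select(ss, design, climate, dispersal, conflict, budget,
                  species_id, persistence),
    change_scenario = "A1FI", reference_scenario = "NC")
  expect_equal(unique(round(cer$ratio, 10)),
               round(prod((1 - e)^(seq_len(n_T) - 1)), 10))
  # indistinguishable scenarios give a ratio of exactly one
  flat <- tidyr::expand_grid(design = "SS", climate = c("NC", "A1FI"),
                             dispersal = "a1", conflict = "uniform",
                             budget = budgets, species_id = "s") |>
    dplyr::mutate(persistence = 0.3)
  same <- climate_effect_ratio(flat, "A1FI", "NC")
  expect_true(all(same$ratio == 1))
})

test_that("a niche vanishing under change drives the ratio to zero everywhere", {
  res <- tidyr::expand_grid(design = "SS", climate = c("NC", "A1FI"),
                            dispersal = "a1", conflict = "uniform",
                            budget = seq(4, 32, by = 4), species_id = "s") |>
    dplyr::mutate(persistence = ifelse(climate == "NC", 0.4, 0))
  cer <- climate_effect_ratio(res, "A1FI", "NC")
  expect_true(all(cer$ratio == 0))
  expect_setequal(cer$budget_quartile, 1:4)
  expect_error(climate_effect_ratio(res, "B1", "NC"), "present")
})
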