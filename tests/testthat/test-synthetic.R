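test_that("a static scenario yields identical surfaces at all periods", {
  cells <- make_grid(6, 6, 10)
  sp <- species_spec("s", c(30, 30), 20, peak_suitability = 0.8)
  nc <- scenario_spec("NC", 0, 0)
  suit <- generate_suitability(cells, sp, nc, n_periods = 4, seed = 3,
                               noise_sd = 0, baseline_cutoff = 0)
  wide <- tidyr::pivot_wider(suit, names_from = "period", values_from = "pos")
  expect_equal(wide$`1`, wide$`2`)
  expect_equal(wide$`1`, wide$`4`)
})

test_that("suitability generation is seeded and bounded", {
  cells <- make_grid(8, 8, 10)
  sp <- species_spec("s", c(40, 40), 25)
  scen <- scenario_spec("X", 8, 0.1)
  a <- generate_suitability(cells, sp, scen, 4, seed = 11)
  b <- generate_suitability(cells, sp, scen, 4, seed = 11)
  c <- generate_suitability(cells, sp, scen, 4, seed = 12)
  expect_identical(a, b)
  expect_false(identical(a, c))
  expect_true(all(a$pos >= 0 & a$pos <= 1))
  expect_error(generate_suitability(cells, sp, scen, 1, seed = 1),
               "n_periods")
})

test_that("the suitability centroid drifts by the shift velocity", {
  cells <- make_grid(30, 30, 5)  # large grid so the niche stays interior
  sp <- species_spec("s", c(75, 75), 15)
  v <- 10
  scen <- scenario_spec("X", v, 0)
  suit <- generate_suitability(cells, sp, scen, 4, seed = 5, noise_sd = 0,
                               baseline_cutoff = 0)
  centroids <- suit |>
    dplyr::left_join(cells, by = "cell_id") |>
    dplyr::group_by(period) |>
    dplyr::summarise(cx = sum(x * pos) / sum(pos),
                     cy = sum(y * pos) / sum(pos))
  steps <- sqrt(diff(centroids$cx)^2 + diff(centroids$cy)^2)
  expect_true(all(abs(steps - v) < 5))  # within one cell size
})

test_that("cost layers include an exact uniform layer and an additive total", {
  cells <- make_grid(5, 5, 10)
  costs <- generate_costs(cells, c("agriculture", "forestry"), 4,
                          autocorr_range = 20, trend = 0.05, seed = 2)
  unif <- costs[costs$activity == "uniform", ]
  expect_true(all(unif$cost == 1))
  expect_identical(nrow(unif), 100L)
  total <- costs[costs$activity == "total", ] |>
    dplyr::arrange(cell_id, period)
  summed <- costs[costs$activity %in% c("agriculture", "forestry"), ] |>
    dplyr::group_by(cell_id, period) |>
    dplyr::summarise(cost = sum(cost), .groups = "drop") |>
    dplyr::arrange(cell_id, period)
  expect_equal(total$cost, summed$cost)
  expect_true(all(costs$cost >= 0))
  expect_error(generate_costs(cells, character(0)), "nonempty")
})

test_that("a zero trend keeps per-period cost means equal", {
  cells <- make_grid(6, 6, 10)
  costs <- generate_costs(cells, "agriculture", 4, autocorr_range = 20,
                          trend = 0, seed = 9)
  mu <- costs[costs$activity == "agriculture", ] |>
    dplyr::group_by(period) |>
    dplyr::summarise(m = mean(cost))
  expect_equal(diff(range(mu$m)), 0, tolerance = 1e-12)
})

test_that("make_study delivers the configured shapes deterministically", {
  cfg <- study_config(n_species = 3, nx = 8, ny = 8)
  st <- make_study(cfg, seed = 21)
  expect_named(st, c("NC", "B1", "A1FI"))
  expect_identical(nrow(st$NC$cells), 64L)
  expect_identical(nrow(st$NC$species), 3L)
  expect_identical(length(st$NC$periods), 4L)
  expect_identical(nrow(st$NC$suitability), 3L * 64L * 4L)
  # bit-identical regeneration, including CSV serialisation
  st2 <- make_study(cfg, seed = 21)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_landscape(st$A1FI, d1)
  write_landscape(st2$A1FI, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  # default demo config: 3 scenarios x 10 species x 4 periods on 20 x 20
  cfg0 <- study_config()
  expect_identical(cfg0$n_species, 10)
  expect_identical(cfg0$nx * cfg0$ny, 400)
  expect_identical(nrow(cfg0$scenarios), 3L)
})

test_that("footprint fraction 0 leaves the landscape unfiltered", {
  cfg <- study_config(n_species = 2, nx = 6, ny = 6, footprint_fraction = 0)
  st <- make_study(cfg, seed = 4)
  expect_identical(apply_footprint_filter(st$NC), st$NC)
  cfg2 <- study_config(n_species = 2, nx = 6, ny = 6, footprint_fraction = 0.2)
  st2 <- make_study(cfg2, seed = 4)
  f <- apply_footprint_filter(st2$NC)
  expect_lt(nrow(f$cells), 36L)
})

test_that("prevalence scales translate into summed baseline suitability", {
  cells <- make_grid(20, 20, 10)
  common <- species_spec("hi", c(100, 100), 30, peak_suitability = 0.005,
                         prevalence_scale = 100)
  rare <- species_spec("lo", c(100, 100), 30, peak_suitability = 0.005,
                       prevalence_scale = 1)
  nc <- scenario_spec("NC", 0, 0)
  s_hi <- generate_suitability(cells, common, nc, 4, seed = 8, noise_sd = 0,
                               baseline_cutoff = 0)
  s_lo <- generate_suitability(cells, rare, nc, 4, seed = 8, noise_sd = 0,
                               baseline_cutoff = 0)
  ratio <- sum(s_hi$pos[s_hi$period == 1]) / sum(s_lo$pos[s_lo$period == 1])
  expect_equal(ratio, 100, tolerance = 0.05)
})

test_that("duplicate species ids are rejected", {
  sp <- dplyr::bind_rows(species_spec("a", c(10, 10), 10),
                         species_spec("a", c(20, 20), 10))
  expect_error(make_study(study_config(n_species = 2, nx = 4, ny = 4),
                          seed = 1, species = sp),
               "duplicate")
})

test_that("harsher scenarios depress best-corridor persistence of a sedentary species", {
  # stationary species (tiny d_max relative to the shift velocity)
  cfg <- study_config(n_species = 1, nx = 12, ny = 12, footprint_fraction = 0)
  sp <- species_spec("s", c(60, 60), 25, peak_suitability = 0.9, d_max = 10)
  st <- make_study(cfg, seed = 6, species = sp)
  best <- purrr::map_dbl(st, function(L) {
    e <- build_pds_edges(L$cells, calibrate_kernel(10, 0.05))
    enumerate_candidates(L, "s", e, K = 1)$persistence
  })
  expect_gt(best[["NC"]], best[["B1"]])
  expect_gt(best[["B1"]], best[["A1FI"]])
})
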