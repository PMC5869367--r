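#' Climate scenario specification
#'
#' A scenario moves each species' climatic niche centre at a fixed velocity
#' (km per period, direction drawn per species) and erodes peak suitability by
#' a fixed fraction per period. A no-change scenario has zero velocity and
#' zero erosion; harsher scenarios get larger values of both.
#'
#' @param label Scenario label, e.g. `"NC"`, `"B1"`, `"A1FI"`.
#' @param shift_velocity Niche-centre displacement, km per period (>= 0).
#' @param suitability_erosion Fraction of suitability lost per period, in
#'   `[0, 1)`.
#' @return A one-row tibble.
#' @export
scenario_spec <- function(label, shift_velocity = 0, suitability_erosion = 0) {
  stopifnot(shift_velocity >= 0,
            suitability_erosion >= 0, suitability_erosion < 1)
  tibble::tibble(label = label, shift_velocity = shift_velocity,
                 suitability_erosion = suitability_erosion)
}

#' Species specification for the synthetic generator
#'
#' Each species occupies a Gaussian climatic niche on the plane. The
#' `prevalence_scale` multiplier lets species differ by orders of magnitude in
#' summed baseline suitability, mirroring the spread of prevalence found in
#' real multi-species datasets.
#'
#' @param species_id Species label.
#' @param niche_center Length-2 numeric, niche centre (x, y) in km.
#' @param niche_width Gaussian niche standard deviation, km (> 0).
#' @param peak_suitability Suitability at the niche centre, in (0, 1].
#' @param prevalence_scale Multiplier on the whole surface (clipped at 1).
#' @param d_max Maximum dispersal distance per period, km.
#' @return A one-row tibble (`center_x`, `center_y`, ... columns).
#' @export
species_spec <- function(species_id, niche_center, niche_width,
                         peak_suitability = 0.9, prevalence_scale = 1,
                         d_max = 30) {
  stopifnot(length(niche_center) == 2, niche_width > 0,
            peak_suitability > 0, peak_suitability <= 1,
            prevalence_scale > 0, d_max > 0)
  tibble::tibble(
    species_id = species_id,
    center_x = niche_center[1], center_y = niche_center[2],
    niche_width = niche_width, peak_suitability = peak_suitability,
    prevalence_scale = prevalence_scale, d_max = d_max
  )
}

#' Generate a suitability cube for one species under one scenario
#'
#' The surface at period `t` is a Gaussian niche centred at
#' `center + (t - 1) * shift_velocity` along a fixed per-species direction,
#' scaled by `(1 - erosion)^(t - 1)` and by `peak_suitability *
#' prevalence_scale`, plus seeded Gaussian noise, clipped to `[0, 1]`.
#' Baseline cells below `baseline_cutoff` are set to 0, emulating cells with
#' no species records in the baseline period.
#'
#' @param cells Grid tibble (`cell_id`, `x`, `y`).
#' @param species One-row tibble from [species_spec()].
#' @param scenario One-row tibble from [scenario_spec()].
#' @param n_periods Number of periods T (>= 2).
#' @param seed Integer seed; the same seed reproduces the cube bit for bit and
#'   is also used to draw the (scenario-independent) shift direction, so
#'   scenarios differ only through velocity and erosion.
#' @param noise_sd Standard deviation of the additive noise (suitability units).
#' @param baseline_cutoff Baseline occupancy cutoff (pos below it becomes 0 at
#'   t = 1).
#' @return Tibble `cell_id`, `period`, `pos`.
#' @export
generate_suitability <- function(cells, species, scenario, n_periods = 4,
                                 seed = 1, noise_sd = 0.02,
                                 baseline_cutoff = 0.05) {
  if (n_periods < 2) {
    stop("n_periods must be >= 2", call. = FALSE)
  }
  stopifnot(nrow(species) == 1, nrow(scenario) == 1)
  withr::local_seed(seed)
  theta <- stats::runif(1, 0, 2 * pi)  # drawn first: same direction across scenarios
  dir <- c(cos(theta), sin(theta))
  peak <- min(1, species$peak_suitability * species$prevalence_scale)
  out <- purrr::map(seq_len(n_periods), function(t) {
    cx <- species$center_x + (t - 1) * scenario$shift_velocity * dir[1]
    cy <- species$center_y + (t - 1) * scenario$shift_velocity * dir[2]
    d2 <- (cells$x - cx)^2 + (cells$y - cy)^2
    pos <- peak * exp(-d2 / (2 * species$niche_width^2)) *
      (1 - scenario$suitability_erosion)^(t - 1)
    if (noise_sd > 0) pos <- pos + stats::rnorm(nrow(cells), sd = noise_sd)
    pos <- pmin(1, pmax(0, pos))
    if (t == 1) pos[pos < baseline_cutoff] <- 0
    tibble::tibble(cell_id = cells$cell_id, period = t, pos = pos)
  })
  dplyr::bind_rows(out)
}

#' Generate spatially autocorrelated cost layers
#'
#' For each activity a nonnegative, spatially autocorrelated opportunity-cost
#' field is produced by Gaussian-kernel smoothing of seeded white noise
#' (smoothing range `autocorr_range`), exponentiated so costs stay positive,
#' normalised to unit mean at the first period, then propagated with a
#' multiplicative per-period trend. Two derived layers are appended: a
#' `uniform` layer costing exactly 1 per cell-period (so one corridor over T
#' periods costs T), and a `total` layer equal to the element-wise sum of the
#' activity layers (total socioeconomic conflict).
#'
#' @param cells Grid tibble.
#' @param activities Character vector of activity labels (nonempty).
#' @param n_periods Number of periods T.
#' @param autocorr_range Smoothing range, km.
#' @param trend Fractional cost change per period (multiplier `1 + trend`);
#'   costs driven below 0 are clipped at 0 with a warning.
#' @param seed Integer seed.
#' @return Tibble `activity`, `cell_id`, `period`, `cost` containing the
#'   activity layers plus `uniform` and `total`.
#' @export
generate_costs <- function(cells, activities, n_periods = 4,
                           autocorr_range = 25, trend = 0.05, seed = 1) {
  if (length(activities) == 0) {
    stop("activities must be nonempty", call. = FALSE)
  }
  stopifnot(!any(activities %in% c("uniform", "total")))
  withr::local_seed(seed)
  n <- nrow(cells)
  d2 <- as.matrix(stats::dist(cbind(cells$x, cells$y)))^2
  W <- exp(-d2 / (2 * autocorr_range^2))
  W <- W / rowSums(W)
  mult <- 1 + trend
  clipped <- FALSE
  layers <- purrr::map(activities, function(a) {
    z <- as.vector(W %*% stats::rnorm(n))
    z <- z / stats::sd(z)
    base <- exp(0.6 * z)
    base <- base / mean(base)
    purrr::map(seq_len(n_periods), function(t) {
      cost <- base * mult^(t - 1)
      if (any(cost < 0)) {
        clipped <<- TRUE
        cost <- pmax(cost, 0)
      }
      tibble::tibble(activity = a, cell_id = cells$cell_id, period = t,
                     cost = cost)
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  if (clipped) warning("negative trend drove some costs below 0; clipped at 0")
  total <- layers |>
    dplyr::group_by(.data$cell_id, .data$period) |>
    dplyr::summarise(cost = sum(.data$cost), .groups = "drop") |>
    dplyr::mutate(activity = "total")
  uniform <- tidyr::expand_grid(cell_id = cells$cell_id,
                                period = seq_len(n_periods)) |>
    dplyr::mutate(activity = "uniform", cost = 1)
  dplyr::bind_rows(layers, uniform, total) |>
    dplyr::select("activity", "cell_id", "period", "cost") |>
    dplyr::arrange(.data$activity, .data$period, .data$cell_id)
}

#' Configure a synthetic study
#'
#' Defaults describe the demonstration study: a 20 x 20 grid of 10-km cells,
#' four 30-year periods, ten Gaussian-niche species with order-of-magnitude
#' prevalence differences, three climate scenarios (no-change plus a moderate
#' and a severe change scenario), four socioeconomic activities, and a small
#' fraction of heavily disturbed (urban) cells.
#'
#' @param nx,ny Grid dimensions. @param cell_size Cell side, km.
#' @param n_periods Periods T.
#' @param n_species Number of species.
#' @param scenarios Tibble of [scenario_spec()] rows.
#' @param activities Activity labels for the cost layers.
#' @param footprint_fraction Fraction of cells with footprint above 60.
#' @param noise_sd,baseline_cutoff Passed to [generate_suitability()].
#' @param autocorr_range,cost_trend Passed to [generate_costs()].
#' @return A `ccc_study_config` list.
#' @export
study_config <- function(nx = 20, ny = 20, cell_size = 10, n_periods = 4,
                         n_species = 10,
                         scenarios = default_scenarios(),
                         activities = c("agriculture", "pasture",
                                        "forestry", "urban"),
                         footprint_fraction = 0.05,
                         noise_sd = 0.02, baseline_cutoff = 0.05,
                         autocorr_range = 25, cost_trend = 0.05) {
  structure(
    list(nx = nx, ny = ny, cell_size = cell_size, n_periods = n_periods,
         n_species = n_species, scenarios = scenarios,
         activities = activities, footprint_fraction = footprint_fraction,
         noise_sd = noise_sd, baseline_cutoff = baseline_cutoff,
         autocorr_range = autocorr_range, cost_trend = cost_trend),
    class = "ccc_study_config"
  )
}

#' Default scenario set
#'
#' A no-change scenario (zero shift, zero erosion), a moderate-change scenario
#' (6 km/period shift, 8% erosion per period) and a severe-change scenario
#' (12 km/period, 16%). Severity ordering is what matters downstream: the
#' severe scenario dominates the moderate one in both knobs.
#'
#' @return Tibble of scenario rows.
#' @export
default_scenarios <- function() {
  dplyr::bind_rows(
    scenario_spec("NC", 0, 0),
    scenario_spec("B1", 6, 0.08),
    scenario_spec("A1FI", 12, 0.16)
  )
}

#' Generate the landscapes of a synthetic study
#'
#' Draws species niches (centres, widths, peaks, prevalence scales spanning
#' roughly two orders of magnitude, and `d_max` between one and six cell
#' widths), one shared footprint layer and one shared cost set, then builds
#' one landscape per scenario. Per-species suitability noise uses a
#' species-specific subseed, identical across scenarios, so scenarios differ
#' only through niche shift and erosion. Fully deterministic given
#' `(config, seed)`.
#'
#' @param config A [study_config()].
#' @param seed Integer seed.
#' @param species Optional tibble of [species_spec()] rows overriding the
#'   random species draw (must have unique `species_id`s).
#' @return Named list of `ccc_landscape`, one per scenario.
#' @export
make_study <- function(config = study_config(), seed = 1, species = NULL) {
  stopifnot(inherits(config, "ccc_study_config"))
  if (nrow(config$scenarios) < 1 || config$n_species < 1) {
    stop("config needs at least one scenario and one species", call. = FALSE)
  }
  withr::local_seed(seed)
  extent_x <- config$nx * config$cell_size
  extent_y <- config$ny * config$cell_size

  if (is.null(species)) {
    species <- purrr::map(seq_len(config$n_species), function(i) {
      species_spec(
        species_id = sprintf("sp%02d", i),
        niche_center = c(stats::runif(1, 0.2, 0.8) * extent_x,
                         stats::runif(1, 0.2, 0.8) * extent_y),
        niche_width = stats::runif(1, 1.5, 4) * config$cell_size,
        peak_suitability = stats::runif(1, 0.6, 0.95),
        prevalence_scale = 10^stats::runif(1, -2, 0),
        d_max = stats::runif(1, 1, 6) * config$cell_size
      )
    }) |> dplyr::bind_rows()
  }
  if (anyDuplicated(species$species_id)) {
    stop("duplicate species ids in study config", call. = FALSE)
  }

  n <- config$nx * config$ny
  footprint <- stats::runif(n, 0, 55)
  n_urban <- round(config$footprint_fraction * n)
  if (n_urban > 0) {
    urban <- sample.int(n, n_urban)
    footprint[urban] <- stats::runif(n_urban, 61, 100)
  }
  cells <- make_grid(config$nx, config$ny, config$cell_size, footprint)

  # subseeds: deterministic, independent of draw order below
  suit_seeds <- sample.int(.Machine$integer.max, nrow(species))
  cost_seed <- sample.int(.Machine$integer.max, 1)

  costs <- generate_costs(cells, config$activities, config$n_periods,
                          config$autocorr_range, config$cost_trend, cost_seed)
  species_table <- tibble::tibble(species_id = species$species_id,
                                  d_max = species$d_max)
  period_labels <- c("baseline", paste0("+", 30 * seq_len(config$n_periods - 1), "y"))

  out <- purrr::map(seq_len(nrow(config$scenarios)), function(k) {
    scen <- config$scenarios[k, ]
    suit <- purrr::map(seq_len(nrow(species)), function(i) {
      generate_suitability(cells, species[i, ], scen, config$n_periods,
                           seed = suit_seeds[i], noise_sd = config$noise_sd,
                           baseline_cutoff = config$baseline_cutoff) |>
        dplyr::mutate(species_id = species$species_id[i], .before = 1)
    }) |> dplyr::bind_rows()
    ccc_landscape(cells, species_table, suit, costs,
                  periods = period_labels, scenario = scen$label,
                  cell_size = config$cell_size)
  })
  stats::setNames(out, config$scenarios$label)
}
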