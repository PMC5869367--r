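#' Plot persistence against budget
#'
#' One line per (design, climate) combination, faceted by species: how the
#' optimised persistence grows with the available budget, and how the joint
#' multi-species plan tracks (or falls short of) the dedicated single-species
#' optimum.
#'
#' @param results Long results tibble (e.g. `run_experiment()$results`),
#'   optionally pre-filtered to one dispersal level and conflict layer;
#'   remaining levels are averaged.
#' @return A ggplot object.
#' @export
plot_budget_sweep <- function(results) {
  dat <- results |>
    dplyr::group_by(.data$design, .data$climate, .data$budget, .data$species_id) |>
    dplyr::summarise(persistence = mean(.data$persistence), .groups = "drop")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$budget, y = .data$persistence,
                                    colour = .data$climate,
                                    linetype = .data$design)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$species_id), scales = "free_y") +
    ggplot2::labs(x = "budget", y = "persistence score",
                  colour = "climate", linetype = "design") +
    ggplot2::theme_minimal()
}

#' Plot factor effect sizes
#'
#' Dot plot of the relative effect size `Peff` of each planning factor, per
#' species.
#'
#' @param effects Tibble from [effect_sizes()] (rows for one or more species).
#' @return A ggplot object.
#' @export
plot_effect_sizes <- function(effects) {
  ggplot2::ggplot(effects, ggplot2::aes(x = .data$Peff, y = .data$factor,
                                        colour = .data$species)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = expression(P[eff] == P[eff * Delta] / P[eff * m]),
                  y = NULL, colour = "species") +
    ggplot2::theme_minimal()
}

#' Map a species' suitability surface through time
#'
#' @param landscape A `ccc_landscape`.
#' @param species_id Species to map.
#' @return A ggplot object, faceted by period.
#' @export
plot_suitability <- function(landscape, species_id) {
  suit <- landscape$suitability[landscape$suitability$species_id == species_id, ]
  dat <- dplyr::left_join(suit, landscape$cells, by = "cell_id") |>
    dplyr::mutate(period = factor(landscape$periods[.data$period],
                                  levels = landscape$periods))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$x, y = .data$y,
                                    fill = .data$pos)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(ggplot2::vars(.data$period), nrow = 1) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (km)", y = "y (km)", fill = "pos",
                  title = species_id) +
    ggplot2::theme_minimal()
}
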