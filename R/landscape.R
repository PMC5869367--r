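#' Build a regular planar grid of cell centroids
#'
#' Cells are indexed row-major from the lower-left corner, with ids contiguous
#' from 0 and centroid coordinates in kilometres. The planar abstraction is
#' deliberate: dispersal success is modelled on linear geographic distance, so
#' no projection machinery is needed.
#'
#' @param nx,ny Number of columns and rows of cells.
#' @param cell_size Cell side length in km (centroids are spaced by this).
#' @param footprint Optional numeric vector of length `nx * ny` with a
#'   human-disturbance index per cell in `[0, 100]`; defaults to 0.
#' @return A tibble with columns `cell_id`, `x`, `y`, `footprint`.
#' @examples
#' make_grid(3, 3, cell_size = 10)
#' @export
make_grid <- function(nx, ny, cell_size = 10, footprint = 0) {
  stopifnot(nx >= 1, ny >= 1, cell_size > 0)
  n <- nx * ny
  footprint <- rep_len(footprint, n)
  tibble::tibble(
    cell_id = seq_len(n) - 1L,
    x = (rep(seq_len(nx), times = ny) - 0.5) * cell_size,
    y = (rep(seq_len(ny), each = nx) - 0.5) * cell_size,
    footprint = footprint
  )
}

#' Assemble a dynamic landscape
#'
#' A landscape bundles everything a corridor analysis needs: the grid, the
#' species trait table (maximum per-period dispersal distance `d_max`), the
#' per-species / per-period climatic suitability cube `pos` in `[0, 1]`, the
#' per-activity / per-period cost cube, and a scenario label. All cubes are
#' stored as long tibbles.
#'
#' Suitability rows absent for the baseline period are filled with `pos = 0`
#' (cells with no species records); rows absent for later periods are likewise
#' completed with zeros so that every (species, cell, period) triple is present.
#'
#' @param cells Tibble from [make_grid()] (columns `cell_id`, `x`, `y`,
#'   `footprint`).
#' @param species Tibble with columns `species_id`, `d_max` (km per period).
#' @param suitability Tibble with columns `species_id`, `cell_id`, `period`
#'   (integer, 1-based), `pos`.
#' @param costs Tibble with columns `activity`, `cell_id`, `period`, `cost`.
#' @param periods Character vector of period labels; its length sets `T`.
#' @param scenario Scenario label (e.g. `"NC"`, `"B1"`, `"A1FI"`).
#' @param cell_size Cell side length in km.
#' @return An object of class `ccc_landscape`.
#' @export
ccc_landscape <- function(cells, species, suitability, costs,
                          periods = c("baseline", "+30y", "+60y", "+90y"),
                          scenario = "NC", cell_size = 10) {
  cells <- tibble::as_tibble(cells)
  species <- tibble::as_tibble(species)
  suitability <- tibble::as_tibble(suitability)
  costs <- tibble::as_tibble(costs)
  n_T <- length(periods)
  if (n_T < 2) {
    stop("a landscape needs at least two periods (T >= 2)", call. = FALSE)
  }
  check_columns(cells, c("cell_id", "x", "y", "footprint"), "cells")
  check_columns(species, c("species_id", "d_max"), "species")
  check_columns(suitability, c("species_id", "cell_id", "period", "pos"),
                "suitability")
  check_columns(costs, c("activity", "cell_id", "period", "cost"), "costs")

  ids <- sort(cells$cell_id)
  if (anyDuplicated(ids) || !identical(as.integer(ids), seq_along(ids) - 1L)) {
    stop("cell_ids must be unique and contiguous from 0", call. = FALSE)
  }
  if (anyDuplicated(cells[, c("x", "y")])) {
    stop("cell coordinates must be unique", call. = FALSE)
  }
  if (any(species$d_max <= 0)) {
    stop("species d_max must be > 0", call. = FALSE)
  }
  if (anyDuplicated(species$species_id)) {
    stop("duplicate species_id in species table", call. = FALSE)
  }

  bad <- which(suitability$pos < 0 | suitability$pos > 1 | is.na(suitability$pos))
  if (length(bad)) {
    b <- suitability[bad[1], ]
    stop(sprintf(
      "suitability pos out of [0, 1]: species '%s', cell %d, period %d (pos = %s)",
      b$species_id, b$cell_id, b$period, format(b$pos)
    ), call. = FALSE)
  }
  if (any(costs$cost < 0 | is.na(costs$cost))) {
    stop("costs must be nonnegative", call. = FALSE)
  }
  if (any(suitability$period < 1 | suitability$period > n_T) ||
      any(costs$period < 1 | costs$period > n_T)) {
    stop("period indices must lie in 1..T", call. = FALSE)
  }

  # complete the cube: unrecorded (species, cell, period) triples carry pos = 0
  full <- tidyr::expand_grid(
    species_id = species$species_id,
    cell_id = cells$cell_id,
    period = seq_len(n_T)
  )
  suitability <- dplyr::left_join(
    full,
    dplyr::mutate(suitability,
                  cell_id = as.integer(.data$cell_id),
                  period = as.integer(.data$period)),
    by = c("species_id", "cell_id", "period")
  )
  suitability$pos[is.na(suitability$pos)] <- 0

  structure(
    list(
      cells = cells,
      species = species,
      suitability = suitability,
      costs = costs,
      periods = as.character(periods),
      scenario = scenario,
      cell_size = cell_size
    ),
    class = "ccc_landscape"
  )
}

check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(sprintf("%s table is missing required column(s): %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

#' @export
print.ccc_landscape <- function(x, ...) {
  cat("<ccc_landscape> scenario:", x$scenario, "\n")
  cat("  ", nrow(x$cells), " cells (", x$cell_size, " km), ",
      length(x$periods), " periods, ",
      nrow(x$species), " species, ",
      dplyr::n_distinct(x$costs$activity), " cost layers\n", sep = "")
  invisible(x)
}

#' Number of periods in a landscape
#' @param landscape A `ccc_landscape`.
#' @return Integer period count.
#' @export
n_periods <- function(landscape) length(landscape$periods)

#' Write / read a landscape as a directory of CSV files
#'
#' The on-disk format is four comma-delimited UTF-8 tables:
#' `cells.csv` (`cell_id,x,y,footprint`), `species.csv` (`species_id,d_max`),
#' `suitability.csv` (`species_id,cell_id,period,pos`) and
#' `costs.csv` (`activity,cell_id,period,cost`), plus `meta.csv` holding the
#' period labels, scenario and cell size. `read_landscape()` validates on load
#' and reports the offending row when a suitability value falls outside
#' `[0, 1]`; missing baseline suitability rows load as zero.
#'
#' @param landscape A `ccc_landscape`.
#' @param dir Directory to write to / read from (created if needed).
#' @return `write_landscape()` returns `dir` invisibly; `read_landscape()`
#'   returns a `ccc_landscape`.
#' @export
write_landscape <- function(landscape, dir) {
  stopifnot(inherits(landscape, "ccc_landscape"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(landscape$cells, file.path(dir, "cells.csv"))
  readr::write_csv(landscape$species, file.path(dir, "species.csv"))
  readr::write_csv(landscape$suitability, file.path(dir, "suitability.csv"))
  readr::write_csv(landscape$costs, file.path(dir, "costs.csv"))
  meta <- tibble::tibble(
    key = c("scenario", "cell_size", paste0("period_", seq_along(landscape$periods))),
    value = c(landscape$scenario, format(landscape$cell_size), landscape$periods)
  )
  readr::write_csv(meta, file.path(dir, "meta.csv"))
  invisible(dir)
}

#' @rdname write_landscape
#' @export
read_landscape <- function(dir) {
  paths <- file.path(dir, c("cells.csv", "species.csv", "suitability.csv",
                            "costs.csv", "meta.csv"))
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop("missing landscape file(s): ", paste(basename(missing), collapse = ", "),
         call. = FALSE)
  }
  cells <- readr::read_csv(paths[1], show_col_types = FALSE,
                           col_types = readr::cols(cell_id = readr::col_integer()))
  species <- readr::read_csv(paths[2], show_col_types = FALSE)
  suitability <- readr::read_csv(paths[3], show_col_types = FALSE,
                                 col_types = readr::cols(
                                   cell_id = readr::col_integer(),
                                   period = readr::col_integer()))
  costs <- readr::read_csv(paths[4], show_col_types = FALSE,
                           col_types = readr::cols(
                             cell_id = readr::col_integer(),
                             period = readr::col_integer()))
  meta <- readr::read_csv(paths[5], show_col_types = FALSE,
                          col_types = readr::cols(.default = readr::col_character()))
  get_meta <- function(k) meta$value[meta$key == k]
  periods <- meta$value[grepl("^period_", meta$key)]
  ccc_landscape(
    cells = cells, species = species, suitability = suitability, costs = costs,
    periods = periods, scenario = get_meta("scenario"),
    cell_size = as.numeric(get_meta("cell_size"))
  )
}

#' Exclude heavily human-disturbed cells
#'
#' Cells whose human-footprint index exceeds `threshold` (strictly greater;
#' 60 characterises urban landscapes) are treated as unsuitable for
#' conservation across all periods and dropped from the grid, the suitability
#' cube and the cost cube. The operation is idempotent and never alters the
#' values attached to retained cells.
#'
#' @param landscape A `ccc_landscape` whose cells carry a `footprint` column.
#' @param threshold Exclusion threshold on the footprint index (default 60;
#'   cells with footprint exactly at the threshold are retained).
#' @return The filtered `ccc_landscape`; retained cells are re-indexed to keep
#'   ids contiguous from 0 (the original id is preserved in a `source_cell`
#'   column of `cells`).
#' @export
apply_footprint_filter <- function(landscape, threshold = 60) {
  stopifnot(inherits(landscape, "ccc_landscape"))
  keep <- landscape$cells$footprint <= threshold
  if (!any(keep)) {
    stop("footprint filter removed every cell: empty study region", call. = FALSE)
  }
  if (all(keep)) {
    return(landscape)
  }
  kept <- landscape$cells[keep, ]
  remap <- stats::setNames(seq_len(nrow(kept)) - 1L, kept$cell_id)
  source_col <- if ("source_cell" %in% names(kept)) kept$source_cell else kept$cell_id
  cells <- dplyr::mutate(kept,
                         source_cell = source_col,
                         cell_id = unname(remap[as.character(.data$cell_id)]))
  suit <- landscape$suitability[landscape$suitability$cell_id %in% kept$cell_id, ]
  suit$cell_id <- unname(remap[as.character(suit$cell_id)])
  costs <- landscape$costs[landscape$costs$cell_id %in% kept$cell_id, ]
  costs$cell_id <- unname(remap[as.character(costs$cell_id)])
  out <- landscape
  out$cells <- cells
  out$suitability <- suit
  out$costs <- costs
  out
}
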