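#' Calibrate a dispersal-success curve
#'
#' Dispersal success is modelled with a negative-exponential kernel
#' `pds(d) = exp(-alpha * d)`, the standard one-parameter distance-decay
#' kernel with `pds(0) = 1`. The decay rate is calibrated so that success at
#' the species' maximum per-period dispersal distance equals `p_at_dmax`:
#' `alpha = -log(p_at_dmax) / d_max`. The conventional curves are 5%, 10% and
#' 15% success at `d_max` (increasingly permissive); beyond `d_max` the kernel
#' is truncated to 0.
#'
#' @param d_max Maximum dispersal distance per period, km (> 0).
#' @param p_at_dmax Success probability at `d_max`, strictly in (0, 1).
#' @return A `dispersal_kernel` object.
#' @examples
#' k <- calibrate_kernel(20, 0.05)
#' pds(k, c(0, 10, 20, 25))
#' @export
calibrate_kernel <- function(d_max, p_at_dmax) {
  if (!is.numeric(d_max) || d_max <= 0) {
    stop("d_max must be > 0", call. = FALSE)
  }
  if (!is.numeric(p_at_dmax) || p_at_dmax <= 0 || p_at_dmax >= 1) {
    stop("p_at_dmax must lie strictly in (0, 1)", call. = FALSE)
  }
  structure(
    list(d_max = d_max, p_at_dmax = p_at_dmax,
         alpha = -log(p_at_dmax) / d_max, mode = "kernel"),
    class = "dispersal_kernel"
  )
}

#' Non-dispersal kernel
#'
#' Models a species unable to track climate: it may only stay in place, with
#' certainty. Only self-edges (weight 1) are generated, so a corridor's
#' persistence reduces to the product of suitabilities in one fixed cell.
#'
#' @return A `dispersal_kernel` object in non-dispersal mode.
#' @export
nondispersal_kernel <- function() {
  structure(
    list(d_max = 0, p_at_dmax = NA_real_, alpha = Inf, mode = "nondispersal"),
    class = "dispersal_kernel"
  )
}

#' @export
print.dispersal_kernel <- function(x, ...) {
  if (x$mode == "nondispersal") {
    cat("<dispersal_kernel> nondispersal (self-edges only)\n")
  } else {
    cat(sprintf("<dispersal_kernel> exp(-%.4f d), d_max %.4g km, pds(d_max) = %.4g\n",
                x$alpha, x$d_max, x$p_at_dmax))
  }
  invisible(x)
}

#' Evaluate a dispersal kernel
#'
#' @param kernel A `dispersal_kernel`.
#' @param distance Numeric vector of distances, km.
#' @return Dispersal-success probabilities; 0 beyond `d_max` (non-dispersal
#'   mode: 1 at distance 0, else 0).
#' @export
pds <- function(kernel, distance) {
  stopifnot(inherits(kernel, "dispersal_kernel"))
  if (kernel$mode == "nondispersal") {
    return(ifelse(distance == 0, 1, 0))
  }
  ifelse(distance <= kernel$d_max, exp(-kernel$alpha * distance), 0)
}

#' Build the per-species dispersal edge set
#'
#' Enumerates ordered cell pairs whose centroid (Euclidean) distance does not
#' exceed the kernel's `d_max`, weighted by dispersal success. Self-edges
#' (distance 0, weight 1) are always present; pairs beyond `d_max` are omitted
#' (success treated as 0). In non-dispersal mode only the self-edges remain.
#'
#' @param cells Tibble with `cell_id`, `x`, `y` (e.g. `landscape$cells`).
#' @param kernel A `dispersal_kernel`.
#' @return A tibble with columns `from`, `to`, `pds`, one row per directed
#'   feasible transition.
#' @export
build_pds_edges <- function(cells, kernel) {
  stopifnot(inherits(kernel, "dispersal_kernel"), nrow(cells) >= 1)
  if (kernel$mode == "nondispersal") {
    return(tibble::tibble(from = cells$cell_id, to = cells$cell_id, pds = 1))
  }
  d <- as.matrix(stats::dist(cbind(cells$x, cells$y)))
  idx <- which(d <= kernel$d_max, arr.ind = TRUE)
  tibble::tibble(
    from = cells$cell_id[idx[, 1]],
    to = cells$cell_id[idx[, 2]],
    pds = exp(-kernel$alpha * d[idx])
  ) |>
    dplyr::arrange(.data$from, .data$to)
}
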