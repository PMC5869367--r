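#' Persistence score of one corridor
#'
#' A corridor is a time-ordered cell sequence `u1, ..., uT`, one cell per
#' period. Its persistence score is the product of the per-period suitability
#' values with the between-period dispersal-success probabilities:
#' `pos(u1,1) * pds(u1,u2) * pos(u2,2) * ... * pds(u(T-1),uT) * pos(uT,T)`.
#' A single nonfunctional cell (`pos = 0`) or infeasible transition (absent
#' edge, `pds = 0`) zeroes the score.
#'
#' @param cells_seq Integer vector of cell ids, one per period (length T).
#' @param suitability Tibble `cell_id`, `period`, `pos` for one species (as in
#'   `landscape$suitability` filtered to a species).
#' @param edges Edge tibble `from`, `to`, `pds` from [build_pds_edges()].
#' @return The persistence score (a nonnegative scalar).
#' @examples
#' suit <- tibble::tibble(cell_id = rep(0:1, each = 2), period = rep(1:2, 2),
#'                        pos = c(0.9, 0.8, 0.5, 0.9))
#' edges <- tibble::tibble(from = c(0, 1, 0), to = c(0, 1, 1), pds = c(1, 1, 1))
#' corridor_persistence(c(0, 1), suit, edges)
#' @export
corridor_persistence <- function(cells_seq, suitability, edges) {
  n_T <- max(suitability$period)
  if (length(cells_seq) != n_T) {
    stop(sprintf("corridor length %d does not match the %d periods",
                 length(cells_seq), n_T), call. = FALSE)
  }
  pos_val <- purrr::map_dbl(seq_len(n_T), function(t) {
    v <- suitability$pos[suitability$cell_id == cells_seq[t] &
                           suitability$period == t]
    if (length(v) == 0) 0 else v[1]
  })
  pds_val <- purrr::map_dbl(seq_len(n_T - 1), function(t) {
    v <- edges$pds[edges$from == cells_seq[t] & edges$to == cells_seq[t + 1]]
    if (length(v) == 0) 0 else v[1]
  })
  prod(pos_val) * prod(pds_val)
}

#' Enumerate the top-K candidate corridors for a species
#'
#' Computes the exact K highest-persistence corridors over the time-layered
#' graph by dynamic programming (per cell-period node, the K best partial
#' paths are kept, in log space). Zero-persistence corridors are never
#' candidates; if fewer than K positive-persistence corridors exist, all are
#' returned. Ties in persistence break lexicographically by cell sequence, so
#' output is deterministic.
#'
#' @param landscape A `ccc_landscape`.
#' @param species_id Species to enumerate for.
#' @param edges Edge tibble from [build_pds_edges()] built on
#'   `landscape$cells` with that species' kernel.
#' @param K Number of corridors to keep (default 2000).
#' @return A tibble with columns `species_id`, `rank`, `cell_1` ... `cell_T`,
#'   `persistence`, sorted by persistence descending. Empty (with a warning)
#'   if the species has no positive-persistence corridor.
#' @export
enumerate_candidates <- function(landscape, species_id, edges, K = 2000) {
  stopifnot(inherits(landscape, "ccc_landscape"), K >= 1)
  n_T <- n_periods(landscape)
  n <- nrow(landscape$cells)
  suit <- landscape$suitability[landscape$suitability$species_id == species_id, ]
  if (nrow(suit) == 0) {
    stop("unknown species_id: ", species_id, call. = FALSE)
  }
  pos <- matrix(0, n, n_T)
  pos[cbind(suit$cell_id + 1L, suit$period)] <- suit$pos
  res <- corridor_topk_cpp(pos, as.integer(edges$from), as.integer(edges$to),
                           edges$pds, as.integer(K))
  if (nrow(res$cells) == 0) {
    warning("no positive-persistence corridor for species ", species_id,
            " (unprotectable)")
    cols <- stats::setNames(rep(list(integer()), n_T), paste0("cell_", seq_len(n_T)))
    return(tibble::tibble(species_id = character(), rank = integer(),
                          !!!cols, persistence = numeric()))
  }
  cells <- tibble::as_tibble(res$cells, .name_repair = ~ paste0("cell_", seq_len(n_T)))
  dplyr::bind_cols(
    tibble::tibble(species_id = species_id, rank = seq_len(nrow(cells))),
    cells,
    tibble::tibble(persistence = exp(res$logscore))
  )
}

#' Exhaustive corridor enumeration (testing oracle)
#'
#' Scores every cell sequence of length T by direct product and returns the
#' positive-persistence ones sorted like [enumerate_candidates()]. Intended
#' as an independent oracle on small instances; refuses more than 100,000
#' sequences.
#'
#' @inheritParams enumerate_candidates
#' @return Tibble in the same shape as [enumerate_candidates()].
#' @export
enumerate_all_corridors <- function(landscape, species_id, edges) {
  n <- nrow(landscape$cells)
  n_T <- n_periods(landscape)
  if (n^n_T > 1e5) {
    stop("instance too large for exhaustive enumeration", call. = FALSE)
  }
  suit <- landscape$suitability[landscape$suitability$species_id == species_id, ]
  pos <- matrix(0, n, n_T)
  pos[cbind(suit$cell_id + 1L, suit$period)] <- suit$pos
  pds_m <- matrix(0, n, n)
  pds_m[cbind(edges$from + 1L, edges$to + 1L)] <- edges$pds
  seqs <- as.matrix(expand.grid(rep(list(seq_len(n) - 1L), n_T),
                                KEEP.OUT.ATTRS = FALSE))
  score <- rep(1, nrow(seqs))
  for (t in seq_len(n_T)) score <- score * pos[cbind(seqs[, t] + 1L, t)]
  for (t in seq_len(n_T - 1)) {
    score <- score * pds_m[cbind(seqs[, t] + 1L, seqs[, t + 1] + 1L)]
  }
  keep <- score > 0
  seqs <- seqs[keep, , drop = FALSE]
  score <- score[keep]
  colnames(seqs) <- paste0("cell_", seq_len(n_T))
  out <- dplyr::bind_cols(tibble::tibble(species_id = species_id),
                          tibble::as_tibble(seqs),
                          tibble::tibble(persistence = score))
  out <- dplyr::arrange(out, dplyr::desc(.data$persistence),
                        !!!rlang::syms(paste0("cell_", seq_len(n_T))))
  dplyr::mutate(out, rank = dplyr::row_number(), .after = "species_id")
}

# cell columns of a candidate tibble, as an integer matrix
candidate_cells <- function(candidates) {
  cols <- grep("^cell_[0-9]+$", names(candidates), value = TRUE)
  cols <- cols[order(as.integer(sub("cell_", "", cols)))]
  as.matrix(candidates[, cols])
}
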