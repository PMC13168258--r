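#' Buffer ring around a mask
#'
#' Returns the cells *outside* the mask whose center lies within
#' `distance_km` (Euclidean, cell centers, planar frame) of the center of some
#' included cell — the neighbouring ring used for near-area population
#' estimates. The ring is always disjoint from the mask, and rings are nested
#' in distance.
#'
#' Implemented as a morphological dilation: the set of integer cell offsets
#' whose center displacement is within `distance_km` is precomputed and the
#' mask is shifted by each offset.
#'
#' @param mask a `cell_mask`.
#' @param distance_km buffer distance in km (>= 0); 10 km by default in the
#'   profiling functions, with 5 and 15 km as standard sensitivity values.
#' @return a `cell_mask` containing only the ring cells.
#' @export
buffer_mask <- function(mask, distance_km) {
  if (distance_km < 0) stop("distance_km must be non-negative")
  g <- mask$grid
  inc <- mask$included
  out <- matrix(FALSE, g$n_rows, g$n_cols)
  if (any(inc) && distance_km > 0) {
    r <- floor(distance_km / g$cell_size_km)
    if (r >= 0) {
      for (di in -r:r) for (dj in -r:r) {
        if (di == 0 && dj == 0) next
        if (sqrt(di^2 + dj^2) * g$cell_size_km > distance_km) next
        si <- seq_len(g$n_rows) - di
        sj <- seq_len(g$n_cols) - dj
        ok_i <- si >= 1 & si <= g$n_rows
        ok_j <- sj >= 1 & sj <= g$n_cols
        out[ok_i, ok_j] <- out[ok_i, ok_j] | inc[si[ok_i], sj[ok_j], drop = FALSE]
      }
    }
  }
  out[inc] <- FALSE
  cell_mask(g, out)
}
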