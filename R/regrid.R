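#' Aggregate a raster layer onto a coarser grid
#'
#' Aggregates square blocks of `factor` x `factor` cells into one coarse cell
#' by summing (counts), averaging (continuous) or taking the modal category
#' (categorical). Nodata cells are excluded from sums and means; a coarse cell
#' whose fine block is entirely nodata stays nodata. Mode ties are broken by
#' the lowest category code, for determinism. Summing conserves the global
#' total exactly.
#'
#' @param layer a `raster_layer`.
#' @param factor positive integer; must divide both grid dimensions.
#' @param method "sum", "mean" or "mode"; mode requires a categorical layer,
#'   sum/mean require a count or continuous layer.
#' @return a `raster_layer` on the coarse grid (cell size multiplied by
#'   `factor`).
#' @export
regrid <- function(layer, factor, method = c("sum", "mean", "mode")) {
  method <- match.arg(method)
  g <- layer$grid
  factor <- as.integer(factor)
  if (factor < 1) stop("factor must be a positive integer")
  if (g$n_rows %% factor != 0 || g$n_cols %% factor != 0)
    stop(sprintf(
      "factor %d does not divide grid %d x %d; pad by %d row(s) and %d col(s)",
      factor, g$n_rows, g$n_cols,
      (factor - g$n_rows %% factor) %% factor,
      (factor - g$n_cols %% factor) %% factor))
  if (method == "mode" && layer$kind != "categorical")
    stop("mode aggregation requires a categorical layer")
  if (method != "mode" && layer$kind == "categorical")
    stop("sum/mean aggregation requires a count or continuous layer")
  nr <- g$n_rows %/% factor; nc <- g$n_cols %/% factor
  coarse <- grid_spec(nr, nc, cell_size_km = g$cell_size_km * factor,
                      origin_x_km = g$origin_x_km, origin_y_km = g$origin_y_km,
                      projection_tag = g$projection_tag)
  v <- layer$values
  bi <- (seq_len(g$n_rows) - 1) %/% factor
  bj <- (seq_len(g$n_cols) - 1) %/% factor
  out <- matrix(NA_real_, nr, nc)
  for (I in 0:(nr - 1)) for (J in 0:(nc - 1)) {
    blk <- v[bi == I, bj == J]
    blk <- blk[!is.na(blk)]
    if (!length(blk)) next
    out[I + 1, J + 1] <- switch(method,
      sum = sum(blk),
      mean = mean(blk),
      mode = {
        tab <- table(blk)
        codes <- as.numeric(names(tab))
        min(codes[tab == max(tab)])  # tie -> lowest code
      })
  }
  raster_layer(coarse, out, kind = layer$kind)
}

#' Coarsen an inclusion-frequency layer to a presence grid
#'
#' Mean-aggregates a frequency layer by `factor` and binarizes presence
#' (> 0), the privacy-preserving display used for sensitive territory layers:
#' a coarse block is marked present when the scenario touches any of its fine
#' cells.
#'
#' @param freq a continuous `raster_layer` in `[0, 1]`.
#' @param factor positive integer aggregation factor.
#' @return a continuous 0/1 `raster_layer` on the coarse grid.
#' @export
coarsen_frequency <- function(freq, factor) {
  m <- regrid(freq, factor, method = "mean")
  v <- m$values
  v[!is.na(v)] <- as.numeric(v[!is.na(v)] > 0)
  raster_layer(m$grid, v, kind = "continuous")
}
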