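#' Zonal sum over a mask
#'
#' Sum of a layer's non-nodata values over the included cells. The basic zonal
#' statistic behind every population and area overlay.
#'
#' @param layer a count or continuous `raster_layer`.
#' @param mask a `cell_mask` on the same grid.
#' @return a scalar; 0 for an empty mask.
#' @export
zonal_sum <- function(layer, mask) {
  check_same_grid(layer$grid, mask$grid, "layer and mask")
  if (layer$kind == "categorical") stop("zonal_sum needs a count or continuous layer")
  sum(layer$values[mask$included], na.rm = TRUE)
}

#' Weighted zonal mean over a mask
#'
#' Computes sum(value * weight) / sum(weight) over included cells where both
#' the value and the weight are non-nodata; the population-weighted mean HDI
#' of a mask's residents is the canonical use.
#'
#' @param value a `raster_layer` of values.
#' @param weight a non-negative `raster_layer` of weights (e.g. population).
#' @param mask a `cell_mask` on the same grid.
#' @return a scalar, or `NA` (with a warning) when the total weight is zero.
#' @export
zonal_weighted_mean <- function(value, weight, mask) {
  check_same_grid(value$grid, weight$grid, "value and weight")
  check_same_grid(value$grid, mask$grid, "layers and mask")
  if (any(weight$values < 0, na.rm = TRUE)) stop("weights must be non-negative")
  sel <- mask$included & !is.na(value$values) & !is.na(weight$values)
  w <- weight$values[sel]
  tw <- sum(w)
  if (tw == 0) {
    warning("zonal_weighted_mean: total weight is zero; result undefined")
    return(NA_real_)
  }
  sum(value$values[sel] * w) / tw
}
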