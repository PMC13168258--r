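#' Construct a conservation feature
#'
#' A feature is anything with a per-cell spatial amount and a representation
#' target: a species (area of habitat km2 per cell), an ecoregion (ecoregion
#' area per cell), or a key biodiversity area.
#'
#' @param id feature identifier.
#' @param kind "species", "ecoregion" or "kba".
#' @param amount a non-negative `raster_layer` of km2 per cell.
#' @param target_amount representation target in km2 (must not exceed the
#'   total amount).
#' @param weight positive objective weight (default 1).
#' @return a list of class `conservation_feature`.
#' @export
conservation_feature <- function(id, kind, amount, target_amount, weight = 1) {
  kind <- match.arg(kind, c("species", "ecoregion", "kba"))
  stopifnot(inherits(amount, "raster_layer"))
  if (any(amount$values < 0, na.rm = TRUE)) stop("feature amounts must be >= 0")
  total <- sum(amount$values, na.rm = TRUE)
  if (target_amount > total + 1e-9)
    stop(sprintf("feature %s: target %.6g exceeds total amount %.6g",
                 id, target_amount, total))
  if (weight <= 0) stop("weight must be positive")
  structure(list(id = as.character(id), kind = kind, amount = amount,
                 target_amount = as.numeric(target_amount),
                 weight = as.numeric(weight)),
            class = "conservation_feature")
}

#' Species representation target from range size
#'
#' Piecewise log-linear rule mapping a species' total area of habitat (AOH) to
#' the fraction of it that should be represented: full representation (1.0)
#' below 1,000 km2, 10 percent above 250,000 km2, and log-linear interpolation
#' in between:
#' target = 1 - 0.9 * (log A - log 1000) / (log 250000 - log 1000).
#'
#' @param aoh_total_km2 positive AOH extent(s) in km2 (vectorized).
#' @return target fraction(s) in `[0.1, 1]`.
#' @export
species_target <- function(aoh_total_km2) {
  if (any(!is.finite(aoh_total_km2)) || any(aoh_total_km2 <= 0))
    stop("AOH extent must be positive")
  t <- 1 - 0.9 * (log(aoh_total_km2) - log(1000)) / (log(250000) - log(1000))
  pmin(pmax(t, 0.1), 1)
}
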