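#' Construct a protected/conserved-area record
#'
#' One entry of a protected-area register in the style of the global
#' WDPA/WDOECM databases: a status, a PA/OECM category, an optional
#' UNESCO-MAB biosphere designation flag, a realm, and either a polygon
#' geometry or a point with a reported area.
#'
#' @param id record identifier (text).
#' @param status one of "proposed", "designated", "inscribed", "established",
#'   "adopted".
#' @param category "PA" or "OECM".
#' @param geometry a `c30_geom` (polygon or point).
#' @param designation_flag "none" or "MAB_biosphere".
#' @param realm "terrestrial", "marine" or "coastal".
#' @param reported_area_km2 reported area in km2, or `NA` if unreported.
#' @return a list of class `pa_record`.
#' @export
pa_record <- function(id, status, category, geometry,
                      designation_flag = "none", realm = "terrestrial",
                      reported_area_km2 = NA_real_) {
  status <- match.arg(status, c("proposed", "designated", "inscribed",
                                "established", "adopted"))
  category <- match.arg(category, c("PA", "OECM"))
  designation_flag <- match.arg(designation_flag, c("none", "MAB_biosphere"))
  realm <- match.arg(realm, c("terrestrial", "marine", "coastal"))
  stopifnot(inherits(geometry, "c30_geom"))
  structure(list(id = as.character(id), status = status, category = category,
                 designation_flag = designation_flag, realm = realm,
                 geometry_kind = geometry$type, geometry = geometry,
                 reported_area_km2 = as.numeric(reported_area_km2)),
            class = "pa_record")
}

#' Filter protected-area records with the register's exclusion rules
#'
#' Applies, in order: records with negative reported area are rejected;
#' proposed-status PAs are dropped (OECMs are kept whatever their status
#' flag); MAB biosphere reserves (PA category) are dropped; marine-realm
#' records are dropped (marine portions of coastal records are handled later
#' by clipping to land); point records with a reported area are replaced by an
#' equal-area circle centred on the point (radius sqrt(A/pi), realised as an
#' area-exact 64-gon); point records without a reported area are dropped.
#' Every record receives exactly one audit line.
#'
#' @param records list of `pa_record`s.
#' @return list with `geoms` (kept polygon geometries) and `audit`, a
#'   data.frame of (id, disposition, reason) with disposition in
#'   kept / dropped / buffered_point.
#' @export
filter_records <- function(records) {
  n <- length(records)
  ids <- character(n); disp <- character(n); reason <- character(n)
  geoms <- list()
  for (k in seq_len(n)) {
    r <- records[[k]]
    stopifnot(inherits(r, "pa_record"))
    ids[k] <- r$id
    if (!is.na(r$reported_area_km2) && r$reported_area_km2 < 0) {
      disp[k] <- "dropped"; reason[k] <- "negative_area"; next
    }
    if (r$category == "PA" && r$status == "proposed") {
      disp[k] <- "dropped"; reason[k] <- "proposed"; next
    }
    if (r$category == "PA" && r$designation_flag == "MAB_biosphere") {
      disp[k] <- "dropped"; reason[k] <- "MAB_biosphere"; next
    }
    if (r$realm == "marine") {
      disp[k] <- "dropped"; reason[k] <- "marine"; next
    }
    if (r$geometry_kind == "point") {
      if (is.na(r$reported_area_km2) || r$reported_area_km2 == 0) {
        disp[k] <- "dropped"; reason[k] <- "no_area"; next
      }
      g <- geom_circle(r$geometry$x, r$geometry$y, r$reported_area_km2, id = r$id)
      disp[k] <- "buffered_point"; reason[k] <- ""
      geoms[[length(geoms) + 1]] <- g
      next
    }
    disp[k] <- "kept"; reason[k] <- ""
    geoms[[length(geoms) + 1]] <- r$geometry
  }
  list(geoms = geoms,
       audit = data.frame(id = ids, disposition = disp, reason = reason,
                          stringsAsFactors = FALSE))
}

#' Build the current protected-and-conserved baseline network
#'
#' Filters the records, rasterizes the coverage of the kept geometries, clips
#' to land (marine portions of coastal geometries contribute nothing), and
#' classifies cells with >= 50 percent coverage as protected/conserved.
#'
#' @param records list of `pa_record`s.
#' @param grid a `c30_grid`.
#' @param land optional land `cell_mask`; defaults to the whole grid.
#' @param theta coverage threshold (default 0.5).
#' @return list of class `baseline_network` with `mask`, `coverage_fraction`
#'   (of land), and the per-record `audit`.
#' @export
build_baseline <- function(records, grid, land = NULL, theta = 0.5) {
  if (is.null(land)) land <- cell_mask(grid, matrix(TRUE, grid$n_rows, grid$n_cols))
  check_same_grid(grid, land$grid, "grid and land")
  f <- filter_records(records)
  cov <- rasterize_coverage(f$geoms, grid)
  cov$values[!land$included] <- 0  # clip to land
  mask <- threshold_mask(cov, theta)
  structure(list(mask = mask,
                 coverage_fraction = coverage_fraction(mask, land),
                 audit = f$audit),
            class = "baseline_network")
}

#' @export
print.baseline_network <- function(x, ...) {
  cat(sprintf("<baseline_network> %d cells (%.1f%% of land); %d records: %s\n",
              mask_cells(x$mask), 100 * x$coverage_fraction, nrow(x$audit),
              paste(sprintf("%d %s", table(x$audit$disposition),
                            names(table(x$audit$disposition))), collapse = ", ")))
  invisible(x)
}
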