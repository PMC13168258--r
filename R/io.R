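# Plain-text I/O: ESRI ASCII grids for raster layers and masks (readable by
# any GIS raster engine), GeoJSON for geometry and protected-area record
# lists, CSV for tables.

#' Write a raster layer or mask as an ESRI ASCII grid
#'
#' Masks are written as 0/1. Coordinates are in the grid's planar km frame;
#' rows are written north-down as the format requires.
#'
#' @param x a `raster_layer` or `cell_mask`.
#' @param path output file path (conventionally `.asc`).
#' @param nodata nodata marker value (default -9999).
#' @export
write_ascii_grid <- function(x, path, nodata = -9999) {
  if (inherits(x, "cell_mask")) {
    g <- x$grid; v <- x$included * 1
  } else if (inherits(x, "raster_layer")) {
    g <- x$grid; v <- x$values
  } else stop("x must be a raster_layer or cell_mask")
  v[is.na(v)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", g$n_cols),
               sprintf("nrows %d", g$n_rows),
               sprintf("xllcorner %.10g", g$origin_x_km),
               sprintf("yllcorner %.10g", g$origin_y_km),
               sprintf("cellsize %.10g", g$cell_size_km),
               sprintf("NODATA_value %.10g", nodata)), con)
  for (i in rev(seq_len(g$n_rows)))
    writeLines(paste(format(v[i, ], digits = 12, trim = TRUE), collapse = " "), con)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path file path.
#' @param kind layer kind ("continuous", "categorical", "count"), or "mask"
#'   to return a `cell_mask` of the nonzero cells.
#' @return a `raster_layer` (or `cell_mask` for `kind = "mask"`).
#' @export
read_ascii_grid <- function(path, kind = "continuous") {
  lines <- readLines(path)
  hdr <- list()
  for (k in 1:6) {
    parts <- strsplit(trimws(lines[k]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  vals <- as.numeric(unlist(strsplit(trimws(lines[7:(6 + nr)]), "\\s+")))
  m <- matrix(vals, nr, nc, byrow = TRUE)[rev(seq_len(nr)), , drop = FALSE]
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  g <- grid_spec(nr, nc, cell_size_km = hdr$cellsize,
                 origin_x_km = hdr$xllcorner, origin_y_km = hdr$yllcorner)
  if (kind == "mask") {
    m[is.na(m)] <- 0
    return(cell_mask(g, m != 0))
  }
  raster_layer(g, m, kind)
}

geom_to_geojson <- function(g) {
  if (g$type == "point") {
    list(type = "Point", coordinates = c(g$x, g$y))
  } else {
    ring <- cbind(c(g$x, g$x[1]), c(g$y, g$y[1]))  # close the ring
    list(type = "Polygon", coordinates = list(ring))
  }
}

geojson_to_geom <- function(gj, id = NULL) {
  if (gj$type == "Point") {
    cc <- unlist(gj$coordinates)
    geom_point(cc[1], cc[2], id = id)
  } else if (gj$type == "Polygon") {
    ring <- gj$coordinates[[1]]
    if (is.list(ring)) ring <- do.call(rbind, lapply(ring, unlist))
    n <- nrow(ring)
    if (all(ring[1, ] == ring[n, ])) ring <- ring[-n, , drop = FALSE]
    geom_polygon(ring[, 1], ring[, 2], id = id)
  } else stop("unsupported GeoJSON geometry type: ", gj$type)
}

#' Write protected-area records as GeoJSON
#'
#' Attributes are stored as feature properties named status, category,
#' designation_flag, realm, reported_area_km2.
#'
#' @param records list of `pa_record`s.
#' @param path output path.
#' @export
write_pa_geojson <- function(records, path) {
  feats <- lapply(records, function(r) {
    list(type = "Feature",
         properties = list(id = r$id, status = r$status, category = r$category,
                           designation_flag = r$designation_flag,
                           realm = r$realm,
                           reported_area_km2 = r$reported_area_km2),
         geometry = geom_to_geojson(r$geometry))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Read protected-area records from GeoJSON
#'
#' @param path GeoJSON FeatureCollection with the attribute fields written by
#'   [write_pa_geojson()].
#' @return list of `pa_record`s.
#' @export
read_pa_geojson <- function(path) {
  fc <- jsonlite::read_json(path)
  lapply(fc$features, function(f) {
    p <- f$properties
    area <- p$reported_area_km2
    pa_record(p$id, p$status, p$category,
              geojson_to_geom(f$geometry, id = p$id),
              designation_flag = p$designation_flag, realm = p$realm,
              reported_area_km2 = if (is.null(area)) NA_real_ else as.numeric(area))
  })
}
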