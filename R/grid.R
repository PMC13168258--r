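#' Define an equal-area analysis grid
#'
#' The grid is the common planar equal-area frame all layers, masks and
#' geometries share. Cells are square with side `cell_size_km`, so every cell
#' has the same area (`cell_size_km^2`, 25 km2 at the default 5 km side).
#' Indexing is row-major and 0-based with cell (0,0) at the origin corner; the
#' center of cell (i,j) is at origin + (index + 0.5) * cell_size.
#'
#' @param n_rows,n_cols positive integers, grid dimensions.
#' @param cell_size_km cell side length in km (default 5, i.e. 25 km2 cells).
#' @param origin_x_km,origin_y_km coordinates of the grid origin corner (km).
#' @param projection_tag free-text label for the equal-area planar frame.
#' @return an object of class `c30_grid`.
#' @export
grid_spec <- function(n_rows, n_cols, cell_size_km = 5,
                      origin_x_km = 0, origin_y_km = 0,
                      projection_tag = "synthetic-equal-area") {
  if (n_rows < 1 || n_cols < 1) stop("grid dimensions must be positive")
  if (cell_size_km <= 0) stop("cell_size_km must be positive")
  structure(list(
    n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
    cell_size_km = as.numeric(cell_size_km),
    origin_x_km = as.numeric(origin_x_km),
    origin_y_km = as.numeric(origin_y_km),
    projection_tag = projection_tag
  ), class = "c30_grid")
}

#' @export
print.c30_grid <- function(x, ...) {
  cat(sprintf("<c30_grid> %d x %d cells, %.3g km side (%.3g km2/cell), origin (%g, %g), frame '%s'\n",
              x$n_rows, x$n_cols, x$cell_size_km, cell_area(x),
              x$origin_x_km, x$origin_y_km, x$projection_tag))
  invisible(x)
}

#' Cell area of a grid in km2
#' @param grid a `c30_grid`.
#' @export
cell_area <- function(grid) grid$cell_size_km^2

same_grid <- function(a, b) {
  isTRUE(all.equal(a[c("n_rows", "n_cols", "cell_size_km",
                       "origin_x_km", "origin_y_km")],
                   b[c("n_rows", "n_cols", "cell_size_km",
                       "origin_x_km", "origin_y_km")]))
}

check_same_grid <- function(a, b, what = "layers") {
  if (!same_grid(a, b)) stop(what, " are not on the same grid")
  invisible(TRUE)
}

#' Cell-center coordinates
#'
#' @param grid a `c30_grid`.
#' @return list with matrices `x` and `y` (n_rows x n_cols) of cell-center
#'   coordinates in km.
#' @export
cell_centers <- function(grid) {
  cs <- grid$cell_size_km
  x <- grid$origin_x_km + (seq_len(grid$n_cols) - 0.5) * cs
  y <- grid$origin_y_km + (seq_len(grid$n_rows) - 0.5) * cs
  list(x = matrix(x, grid$n_rows, grid$n_cols, byrow = TRUE),
       y = matrix(y, grid$n_rows, grid$n_cols))
}

#' Construct a raster layer on a grid
#'
#' @param grid a `c30_grid`.
#' @param values numeric matrix (`n_rows` x `n_cols`); `NA` marks nodata.
#' @param kind one of "continuous", "categorical", "count".
#' @return an object of class `raster_layer`.
#' @export
raster_layer <- function(grid, values, kind = c("continuous", "categorical", "count")) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (!identical(dim(values), c(grid$n_rows, grid$n_cols)))
    stop("values shape must equal (n_rows, n_cols)")
  if (kind == "count" && any(values < 0, na.rm = TRUE))
    stop("count layers must be non-negative where not nodata")
  structure(list(grid = grid, values = values, kind = kind),
            class = "raster_layer")
}

#' @export
print.raster_layer <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("<raster_layer:%s> %d x %d, %d nodata cells",
              x$kind, x$grid$n_rows, x$grid$n_cols, sum(is.na(x$values))))
  if (length(v))
    cat(sprintf(", range [%.4g, %.4g]", min(v), max(v)))
  cat("\n")
  invisible(x)
}

#' @export
as.matrix.raster_layer <- function(x, ...) x$values

#' Construct a boolean cell mask on a grid
#'
#' @param grid a `c30_grid`.
#' @param included logical matrix (`n_rows` x `n_cols`); `NA` treated as FALSE.
#' @return an object of class `cell_mask`.
#' @export
cell_mask <- function(grid, included) {
  included <- as.matrix(included)
  if (!identical(dim(included), c(grid$n_rows, grid$n_cols)))
    stop("mask shape must match grid")
  included[is.na(included)] <- FALSE
  storage.mode(included) <- "logical"
  structure(list(grid = grid, included = included), class = "cell_mask")
}

#' @export
print.cell_mask <- function(x, ...) {
  cat(sprintf("<cell_mask> %d x %d, %d cells included (%.4g km2)\n",
              x$grid$n_rows, x$grid$n_cols, mask_cells(x), mask_area(x)))
  invisible(x)
}

#' @export
as.matrix.cell_mask <- function(x, ...) x$included

#' Number of included cells in a mask
#' @param mask a `cell_mask`.
#' @export
mask_cells <- function(mask) sum(mask$included)

#' Area of a mask in km2
#' @param mask a `cell_mask`.
#' @export
mask_area <- function(mask) mask_cells(mask) * cell_area(mask$grid)

#' Fraction of a reference area (usually land) covered by a mask
#' @param mask a `cell_mask`.
#' @param land a `cell_mask` giving the reference area.
#' @export
coverage_fraction <- function(mask, land) {
  check_same_grid(mask$grid, land$grid, "mask and land")
  if (mask_cells(land) == 0) stop("reference land mask is empty")
  mask_cells(mask) / mask_cells(land)
}

# set algebra on masks -- all require a shared grid
#' Mask set operations
#'
#' Union, intersection and difference of two masks on the same grid.
#' @param a,b `cell_mask` objects on the same grid.
#' @name mask-ops
#' @export
mask_union <- function(a, b) {
  check_same_grid(a$grid, b$grid, "masks")
  cell_mask(a$grid, a$included | b$included)
}

#' @rdname mask-ops
#' @export
mask_intersect <- function(a, b) {
  check_same_grid(a$grid, b$grid, "masks")
  cell_mask(a$grid, a$included & b$included)
}

#' @rdname mask-ops
#' @export
mask_diff <- function(a, b) {
  check_same_grid(a$grid, b$grid, "masks")
  cell_mask(a$grid, a$included & !b$included)
}

#' Does mask `a` contain mask `b`?
#' @param a,b `cell_mask` objects on the same grid.
#' @export
mask_contains <- function(a, b) {
  check_same_grid(a$grid, b$grid, "masks")
  !any(b$included & !a$included)
}
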