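# Shared fixtures, built in code.

# tiny grid with 5 km cells
tiny_grid <- function(nr = 3, nc = 3, cs = 5) grid_spec(nr, nc, cs)

full_mask <- function(g) cell_mask(g, matrix(TRUE, g$n_rows, g$n_cols))
empty_mask <- function(g) cell_mask(g, matrix(FALSE, g$n_rows, g$n_cols))

mask_from_cells <- function(g, cells) {
  m <- matrix(FALSE, g$n_rows, g$n_cols)
  m[cells] <- TRUE
  cell_mask(g, m)
}

# independent point-sampling coverage oracle: k x k points per cell, a point
# counts when inside any polygon (union), point-in-polygon via mgcv::in.out
supersample_coverage <- function(geoms, g, k = 100) {
  out <- matrix(0, g$n_rows, g$n_cols)
  cs <- g$cell_size_km
  for (i in seq_len(g$n_rows)) for (j in seq_len(g$n_cols)) {
    px <- g$origin_x_km + (j - 1) * cs + (seq_len(k) - 0.5) * cs / k
    py <- g$origin_y_km + (i - 1) * cs + (seq_len(k) - 0.5) * cs / k
    pts <- cbind(rep(px, each = k), rep(py, k))
    inside <- rep(FALSE, nrow(pts))
    for (gm in geoms) {
      bnd <- cbind(c(gm$x, gm$x[1]), c(gm$y, gm$y[1]))
      inside <- inside | mgcv::in.out(bnd, pts)
    }
    out[i, j] <- mean(inside)
  }
  out
}

# one small default world shared across tests (seed fixed, fast to build)
shared_world <- local({
  w <- NULL
  function() {
    if (is.null(w)) w <<- generate_world(world_config(seed = 42))
    w
  }
})
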