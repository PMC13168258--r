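test_that("coverage rasterization handles full, empty and union cases", {
  g <- tiny_grid(4, 4)
  whole <- geom_rect(-1, -1, 21, 21)
  cov <- rasterize_coverage(list(whole), g)
  expect_equal(cov$values, matrix(1, 4, 4))

  expect_equal(rasterize_coverage(list(), g)$values, matrix(0, 4, 4))

  # overlapping duplicates never exceed 1 (union semantics)
  cov2 <- rasterize_coverage(list(whole, whole, geom_rect(2, 2, 9, 9)), g)
  expect_equal(cov2$values, matrix(1, 4, 4))
})

test_that("triangle coverage matches an independent supersampling oracle", {
  skip_if_not_installed("mgcv")
  g <- tiny_grid(4, 4)
  tri <- geom_polygon(c(1, 19, 4), c(1, 3, 18))
  cov <- rasterize_coverage(list(tri), g)
  oracle <- supersample_coverage(list(tri), g, k = 100)
  expect_lt(max(abs(cov$values - oracle)), 0.01)
  # union of two overlapping shapes against the same oracle
  geoms <- list(tri, geom_rect(6, 2, 14, 12))
  expect_lt(max(abs(rasterize_coverage(geoms, g)$values -
                      supersample_coverage(geoms, g, 100))), 0.01)
})

test_that("invalid geometries are rejected with their record id", {
  g <- tiny_grid()
  bowtie <- geom_polygon(c(0, 10, 0, 10), c(0, 10, 10, 0), id = "bt1")
  expect_error(rasterize_coverage(list(bowtie), g), "bt1")
  expect_error(rasterize_coverage(list(geom_polygon(c(0, 1), c(0, 1), id = "short")),
                                  g), "short")
})

test_that("coverage threshold is inclusive at 50% and excludes nodata", {
  g <- tiny_grid(1, 4)
  cov <- raster_layer(g, matrix(c(0.49, 0.50, 1.0, NA), 1, 4), "continuous")
  m <- threshold_mask(cov)
  expect_equal(as.vector(m$included), c(FALSE, TRUE, TRUE, FALSE))
  expect_error(threshold_mask(cov, theta = 1.5), "\\[0, 1\\]")
})

test_that("aggregation conserves sums, preserves constants, and breaks mode ties low", {
  g <- grid_spec(4, 6, 1)
  set.seed(7)
  counts <- raster_layer(g, matrix(as.numeric(sample(0:50, 24, TRUE)), 4, 6), "count")
  agg <- regrid(counts, 2, "sum")
  expect_identical(sum(agg$values), sum(counts$values))  # bit-for-bit at integers

  const <- raster_layer(g, matrix(0.7, 4, 6), "continuous")
  expect_equal(regrid(const, 2, "mean")$values, matrix(0.7, 2, 3))

  cat4 <- raster_layer(grid_spec(2, 2, 1), matrix(c(1, 2, 1, 3), 2, 2), "categorical")
  expect_equal(regrid(cat4, 2, "mode")$values[1, 1], 1)
  # a clean tie {1,1,3,3} resolves to the lowest code
  tie <- raster_layer(grid_spec(2, 2, 1), matrix(c(1, 3, 3, 1), 2, 2), "categorical")
  expect_equal(regrid(tie, 2, "mode")$values[1, 1], 1)

  expect_error(regrid(counts, 5, "sum"), "pad")
  expect_error(regrid(counts, 2, "mode"), "categorical")
  expect_error(regrid(cat4, 2, "sum"), "count or continuous")
})

test_that("nodata cells drop out of aggregation and all-nodata blocks stay nodata", {
  g <- grid_spec(2, 2, 1)
  v <- matrix(c(2, NA, NA, NA), 2, 2)
  expect_equal(regrid(raster_layer(g, v, "count"), 2, "sum")$values[1, 1], 2)
  allna <- raster_layer(g, matrix(NA_real_, 2, 2), "count")
  expect_true(is.na(regrid(allna, 2, "sum")$values[1, 1]))
})

test_that("buffer ring matches a brute-force center-distance oracle", {
  g <- grid_spec(7, 7, 5)
  m <- mask_from_cells(g, 25)  # center cell
  for (d in c(10, 7.2, 5)) {
    ring <- buffer_mask(m, d)
    cc <- cell_centers(g)
    dd <- sqrt((cc$x - cc$x[25])^2 + (cc$y - cc$y[25])^2)
    oracle <- dd <= d & !m$included
    expect_equal(ring$included, oracle, info = paste("distance", d))
  }
})

test_that("buffers are empty at zero distance, nested in distance, disjoint from the mask", {
  g <- grid_spec(10, 10, 5)
  set.seed(11)
  m <- mask_from_cells(g, sample(100, 6))
  expect_equal(mask_cells(buffer_mask(m, 0)), 0)
  expect_equal(mask_cells(buffer_mask(empty_mask(g), 10)), 0)
  prev <- buffer_mask(m, 5)
  for (d in c(10, 15, 22)) {
    cur <- buffer_mask(m, d)
    expect_true(mask_contains(cur, prev))  # nesting
    expect_equal(mask_cells(mask_intersect(cur, m)), 0)  # disjoint
    prev <- cur
  }
})

test_that("zonal sums match hand enumeration and add over disjoint zones", {
  g <- tiny_grid(3, 3)
  vals <- matrix(1:9, 3, 3)
  lay <- raster_layer(g, vals, "count")
  expect_equal(zonal_sum(lay, empty_mask(g)), 0)
  expect_equal(zonal_sum(lay, full_mask(g)), 45)
  m <- mask_from_cells(g, c(1, 5, 9))  # values 1, 5, 9
  expect_equal(zonal_sum(lay, m), 15)

  # nodata excluded
  vals2 <- vals; vals2[5] <- NA
  expect_equal(zonal_sum(raster_layer(g, vals2, "count"), m), 10)

  # additivity over random disjoint zones
  set.seed(3)
  for (k in 1:10) {
    cells <- sample(9, 6)
    a <- mask_from_cells(g, cells[1:3]); b <- mask_from_cells(g, cells[4:6])
    expect_equal(zonal_sum(lay, a) + zonal_sum(lay, b),
                 zonal_sum(lay, mask_union(a, b)))
  }
  expect_error(zonal_sum(lay, full_mask(grid_spec(2, 2, 5))), "same grid")
})

test_that("weighted zonal mean reduces correctly in constant, point-mass and hand cases", {
  g <- tiny_grid(1, 3)
  val <- raster_layer(g, matrix(c(0.2, 0.5, 0.9), 1, 3), "continuous")
  w_any <- raster_layer(g, matrix(c(3, 1, 6), 1, 3), "count")
  m <- full_mask(g)
  const <- raster_layer(g, matrix(0.7, 1, 3), "continuous")
  expect_equal(zonal_weighted_mean(const, w_any, m), 0.7)

  point <- raster_layer(g, matrix(c(0, 0, 5), 1, 3), "count")
  expect_equal(zonal_weighted_mean(val, point, m), 0.9)

  expect_equal(zonal_weighted_mean(val, w_any, m),
               (0.2 * 3 + 0.5 * 1 + 0.9 * 6) / 10)

  zero <- raster_layer(g, matrix(0, 1, 3), "count")
  expect_warning(res <- zonal_weighted_mean(val, zero, m), "undefined")
  expect_true(is.na(res))
})
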