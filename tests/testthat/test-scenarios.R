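scen_fixture <- function(seed = 42) {
  w <- shared_world()
  b <- build_baseline(w$pa_records, w$grid, land = w$land)
  list(w = w, b = b, cfg = scenario_config(replicates = 10, seed = seed))
}

test_that("biodiversity scenario locks baseline and KBAs and hits the coverage target", {
  fx <- scen_fixture()
  s <- build_biodiversity_scenario(fx$w$features, fx$b, fx$w$kbas, fx$cfg,
                                   fx$w$grid, fx$w$land)
  expect_true(mask_contains(s$mask, fx$b$mask))
  expect_true(mask_contains(s$mask, mask_intersect(fx$w$kbas, fx$w$land)))
  n_land <- mask_cells(fx$w$land)
  expect_lte(abs(mask_cells(s$mask) - round(0.30 * n_land)), 1)
  expect_equal(nrow(s$objective_report), length(fx$w$features))
})

test_that("biodiversity scenario is deterministic across reruns", {
  fx <- scen_fixture()
  s1 <- build_biodiversity_scenario(fx$w$features, fx$b, fx$w$kbas, fx$cfg,
                                    fx$w$grid, fx$w$land)
  s2 <- build_biodiversity_scenario(fx$w$features, fx$b, fx$w$kbas, fx$cfg,
                                    fx$w$grid, fx$w$land)
  expect_identical(s1$mask$included, s2$mask$included)
})

test_that("with no features the budget fills in row-major order", {
  g <- grid_spec(4, 5, 5)
  land <- full_mask(g)
  base <- empty_mask(g)
  kbas <- empty_mask(g)
  cfg <- scenario_config(total_target_fraction = 0.30)
  s <- build_biodiversity_scenario(list(), base, kbas, cfg, g, land)
  # 6 cells: the whole first grid row (row-major 0..4), then cell (1,0)
  expect_equal(mask_cells(s$mask), 6)
  expect_true(all(s$mask$included[1, ]))
  expect_true(s$mask$included[2, 1])
})

test_that("an endemic species' patch is selected before empty cells", {
  g <- grid_spec(4, 5, 5)
  land <- full_mask(g)
  amt <- matrix(0, 4, 5); amt[3:4, 4] <- 25
  f <- conservation_feature("endemic", "species",
                            raster_layer(g, amt, "count"), 50)
  cfg <- scenario_config(total_target_fraction = 0.10)  # budget 2 cells
  s <- build_biodiversity_scenario(list(f), empty_mask(g), empty_mask(g),
                                   cfg, g, land)
  expect_true(all(s$mask$included[3:4, 4]))
})

test_that("an over-target locked-in area is a configuration error", {
  g <- grid_spec(4, 5, 5)
  base <- mask_from_cells(g, 1:10)  # 50% locked
  cfg <- scenario_config(total_target_fraction = 0.30)
  expect_error(build_biodiversity_scenario(list(), base, empty_mask(g), cfg, g,
                                           full_mask(g)), "exceeds")
})

test_that("NCP selection matches a sorting oracle on distinct ranks", {
  g <- grid_spec(2, 5, 5)
  set.seed(9)
  rv <- matrix(sample(1:10), 2, 5)
  rank <- raster_layer(g, rv, "continuous")
  cfg <- scenario_config(total_target_fraction = 0.5)
  s <- build_ncp_scenario(rank, empty_mask(g), cfg, g, full_mask(g))
  oracle <- rv >= sort(rv, decreasing = TRUE)[5]
  expect_equal(s$mask$included, oracle)
  expect_equal(s$captured_value_share, sum(rv[oracle]) / sum(rv))
})

test_that("NCP ties and saturated baselines behave as documented", {
  g <- grid_spec(2, 5, 5)
  uni <- raster_layer(g, matrix(1, 2, 5), "continuous")
  cfg <- scenario_config(total_target_fraction = 0.4)
  s <- build_ncp_scenario(uni, empty_mask(g), cfg, g, full_mask(g))
  # uniform rank: first needed cells in row-major order = first 4 of row 1
  expect_equal(which(s$mask$included), c(1, 3, 5, 7))

  base <- mask_from_cells(g, 1:5)
  s2 <- build_ncp_scenario(uni, base, scenario_config(total_target_fraction = 0.5),
                           g, full_mask(g))
  expect_equal(s2$mask$included, base$included)

  allna <- raster_layer(g, matrix(NA_real_, 2, 5), "continuous")
  expect_error(build_ncp_scenario(allna, base, cfg, g, full_mask(g)), "nodata")
})

test_that("NCP captured share beats random equal-size selections", {
  fx <- scen_fixture()
  s <- build_ncp_scenario(fx$w$ncp_rank, fx$b, fx$cfg, fx$w$grid, fx$w$land)
  rv <- fx$w$ncp_rank$values
  land_cells <- which(fx$w$land$included)
  n_sel <- mask_cells(s$mask)
  set.seed(101)
  rand_share <- mean(replicate(100, {
    pick <- sample(land_cells, n_sel)
    sum(rv[pick], na.rm = TRUE) / sum(rv, na.rm = TRUE)
  }))
  expect_gt(s$captured_value_share, rand_share)
})

test_that("territories scenario never removes ICCA or baseline cells", {
  fx <- scen_fixture()
  s <- build_itt_scenario(fx$w$iplc_lands, fx$w$icca_records, fx$b, fx$w$hmi,
                          fx$cfg, fx$w$grid, fx$w$land)
  expect_true(mask_contains(s$mask, fx$b$mask))
  fixed_in <- mask_intersect(s$fixed, s$mask)
  expect_true(all(s$inclusion_frequency$values[fixed_in$included] == 1))
  n_land <- mask_cells(fx$w$land)
  expect_lte(abs(mask_cells(s$mask) - round(0.30 * n_land)), 1)
  # candidate (non-fixed) cells above the modification threshold are excluded
  cand <- mask_diff(s$mask, s$fixed)
  expect_true(all(fx$w$hmi$values[cand$included] <= fx$cfg$hmi_threshold))
})

test_that("when nothing needs removal all replicates are identical", {
  g <- grid_spec(4, 5, 5)
  land <- full_mask(g)
  # one territory covering exactly 6 cells = the 30% target of 20 cells
  terr <- list(list(geometry = geom_rect(0, 0, 15, 10), rights_flag = "none"))
  hmi <- raster_layer(g, matrix(0, 4, 5), "continuous")
  cfg <- scenario_config(total_target_fraction = 0.30, replicates = 5)
  s <- build_itt_scenario(terr, list(), empty_mask(g), hmi, cfg, g, land)
  expect_true(all(s$inclusion_frequency$values %in% c(0, 1)))
  for (r in 2:5) expect_identical(s$replicate_masks[[r]], s$replicate_masks[[1]])
})

test_that("rights-flagged territories are excluded and point ICCAs buffered", {
  g <- grid_spec(4, 5, 5)
  land <- full_mask(g)
  hmi <- raster_layer(g, matrix(0, 4, 5), "continuous")
  cfg <- scenario_config(total_target_fraction = 0.9, replicates = 2)
  terr <- list(list(geometry = geom_rect(0, 0, 12, 10), rights_flag = "subject_to_other_special_rights"))
  icca <- list(pa_record("icca_pt", "established", "OECM", geom_point(17.5, 7.5),
                         reported_area_km2 = 80))
  s <- build_itt_scenario(terr, icca, empty_mask(g), hmi, cfg, g, land)
  # flagged territory contributes nothing; buffered 80 km2 point covers its cell
  expect_false(any(s$mask$included[, 1:2]))
  expect_true(s$mask$included[2, 4])  # cell containing the point (x 17.5, y 7.5)
})

test_that("an unreachable target (fixed area too large) errors", {
  g <- grid_spec(4, 5, 5)
  land <- full_mask(g)
  hmi <- raster_layer(g, matrix(0, 4, 5), "continuous")
  base <- mask_from_cells(g, 1:12)  # 60% fixed
  cfg <- scenario_config(total_target_fraction = 0.30, replicates = 2)
  expect_error(build_itt_scenario(list(), list(), base, hmi, cfg, g, land),
               "non-removable")
})

test_that("territory inclusion frequencies follow the uniform-removal sampling law", {
  g <- grid_spec(20, 20, 5)
  land <- full_mask(g)
  hmi <- raster_layer(g, matrix(0, 20, 20), "continuous")
  base <- mask_from_cells(g, 1:40)                    # f = 40 fixed cells
  terr <- list(list(geometry = geom_rect(0, 0, 100, 100), rights_flag = "none"))
  R <- 200
  cfg <- scenario_config(total_target_fraction = 0.40, replicates = R, seed = 7)
  s <- build_itt_scenario(terr, list(), base, hmi, cfg, g, land)
  m <- 360                                            # removable cells
  k <- 160 - 40                                       # kept beyond fixed
  p <- k / m
  se <- sqrt(p * (1 - p) / R)
  freq <- s$inclusion_frequency$values[!base$included]
  expect_true(mean(abs(freq - p) <= 3 * se) >= 0.99)
})

test_that("frequency coarsening marks any touched coarse block as present", {
  g <- grid_spec(4, 4, 5)
  z <- matrix(0, 4, 4)
  expect_equal(sum(coarsen_frequency(raster_layer(g, z, "continuous"), 2)$values), 0)
  z[3, 2] <- 0.4
  cf <- coarsen_frequency(raster_layer(g, z, "continuous"), 2)
  expect_equal(cf$values, matrix(c(0, 1, 0, 0), 2, 2))
  # random fixture equals the regrid-then-binarize oracle
  set.seed(13)
  zr <- matrix(runif(16) * rbinom(16, 1, 0.3), 4, 4)
  cf2 <- coarsen_frequency(raster_layer(g, zr, "continuous"), 2)
  oracle <- regrid(raster_layer(g, zr, "continuous"), 2, "mean")
  expect_equal(cf2$values, (oracle$values > 0) * 1)
})
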