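# hand-buildable 3x3 social world; every layer set explicitly
hand_layers <- function() {
  g <- grid_spec(3, 3, 5)
  lay <- function(v, kind = "count") raster_layer(g, matrix(v, 3, 3, byrow = TRUE), kind)
  # rows are grid rows 1..3 bottom-up; byrow=TRUE lists them row by row
  pop0 <- lay(c(100, 200, 0,
                50, 400, 10,
                0, 0, 30))
  pop1 <- lay(c(110, 220, 0,
                60, 480, 10,
                0, 0, 33))
  hdi <- lay(c(0.54, 0.55, 0.30,
               0.80, 0.70, 0.79,
               NA, 0.95, 0.20), "continuous")
  wh <- lay(c(40, 10, 0,
              0, 0, 5,
              0, 0, 0))
  nonf <- lay(rep(15, 9)); small <- lay(rep(6, 9)); large <- lay(rep(4, 9))
  ls <- lay(c(1, 0, 1,
              2, 1, 0,
              0, 3, 1), "categorical")
  tropics <- cell_mask(g, matrix(c(TRUE, TRUE, TRUE,
                                   FALSE, FALSE, FALSE,
                                   FALSE, FALSE, FALSE), 3, 3, byrow = TRUE))
  cont <- lay(c(1, 1, 2,
                1, 2, 2,
                1, 2, 2), "categorical")
  social_layers(pop0, pop1, hdi, wh, nonf, small, large, ls,
                livestock_only_code = 1, tropics = tropics, continents = cont,
                continent_names = c("1" = "west", "2" = "east"),
                land = full_mask(g))
}

test_that("HDI category boundaries are half-open at the printed cutoffs", {
  lay <- hand_layers()
  g <- lay$population_t0$grid
  # cells with hdi 0.54, 0.55, 0.80 (grid positions in row 1 and row 2)
  p1 <- social_profile(cell_mask(g, matrix(c(TRUE, rep(FALSE, 8)), 3, 3)), lay)
  expect_equal(unname(p1$hdi_category_pops["low"]), 100)
  m2 <- matrix(FALSE, 3, 3); m2[1, 2] <- TRUE  # hdi 0.55
  p2 <- social_profile(cell_mask(g, m2), lay)
  expect_equal(unname(p2$hdi_category_pops["medium"]), 200)
  m3 <- matrix(FALSE, 3, 3); m3[2, 1] <- TRUE  # hdi 0.80
  p3 <- social_profile(cell_mask(g, m3), lay)
  expect_equal(unname(p3$hdi_category_pops["very_high"]), 50)
})

test_that("a single-category mask concentrates 100% of the resident population", {
  g <- grid_spec(2, 2, 5)
  pop <- raster_layer(g, matrix(25, 2, 2), "count")
  hdi <- raster_layer(g, matrix(0.6, 2, 2), "continuous")
  zero <- raster_layer(g, matrix(0, 2, 2), "count")
  ls <- raster_layer(g, matrix(0, 2, 2), "categorical")
  lay <- social_layers(pop, pop, hdi, zero, zero, zero, zero, ls, 1,
                       tropics = empty_mask(g), continents = ls,
                       land = full_mask(g))
  p <- social_profile(full_mask(g), lay)
  expect_equal(unname(p$hdi_category_pct["medium"]), 100)
  expect_equal(sum(p$hdi_category_pops), p$resident_pop)
  expect_equal(p$mean_hdi, 0.6)
})

test_that("the full profile matches cell-by-cell hand enumeration", {
  lay <- hand_layers()
  g <- lay$population_t0$grid
  # mask: bottom row (grid row 1) plus cell (2,2)
  m <- matrix(FALSE, 3, 3); m[1, ] <- TRUE; m[2, 2] <- TRUE
  p <- social_profile(cell_mask(g, m), lay, buffer_km = 5)
  # residents: 100 + 200 + 0 + 400
  expect_equal(p$resident_pop, 700)
  # ring at 5 km: all remaining cells adjoin the mask orthogonally except (3,1)?
  # centers: ring = cells within 5 km of a mask cell center, not in mask:
  # (2,1) d=5 yes, (2,3) d=5 yes from (1,3); (3,2) d=5 from (2,2);
  # (3,1),(3,3) only diagonal (7.07) -> out
  expect_equal(p$buffer_pop, 50 + 10 + 0)
  # categories: 0.54->low(100), 0.55->medium(200), 0.30->low(0), 0.70->high(400)
  expect_equal(unname(p$hdi_category_pops), c(100, 200, 400, 0))
  expect_equal(unname(p$hdi_category_pct), 100 * c(100, 200, 400, 0) / 700)
  expect_equal(p$mean_hdi,
               (0.54 * 100 + 0.55 * 200 + 0.70 * 400) / 700)
  # tropics = grid row 1; wild harvest (40+10)/(100+200+0)
  expect_equal(p$tropical_resident_pop, 300)
  expect_equal(p$wildharvest_share, 100 * 50 / 300)
  # farm shares on 4 cells of 25 km2
  expect_equal(unname(p$farm_shares),
               100 * c(15, 6, 4) * 4 / (4 * 25))
  # livestock-only cells in mask: (1,1) code 1, (1,3) code 1, (2,2) code 1 -> 3/4
  expect_equal(p$rangeland_share, 100 * 3 / 4)
  # growth: pop1 mask sum = 110+220+0+480 = 810
  expect_equal(p$growth_pct, 100 * (810 - 700) / 700)
})

test_that("HDI category populations always partition the resident population", {
  w <- shared_world()
  set.seed(21)
  for (k in 1:5) {
    m <- cell_mask(w$grid, matrix(runif(3600) < 0.2, 60, 60) & w$land$included)
    p <- social_profile(m, w$layers)
    pop_hdi_cells <- sum(w$layers$population_t0$values[
      m$included & !is.na(w$layers$hdi$values)], na.rm = TRUE)
    expect_equal(sum(p$hdi_category_pops), pop_hdi_cells)
    if (pop_hdi_cells > 0)
      expect_equal(sum(p$hdi_category_pct), 100, tolerance = 1e-9)
  }
})

test_that("farm shares sum to 100 when the components tile the cell", {
  w <- shared_world()
  m <- mask_intersect(w$land, w$layers$tropics)
  p <- social_profile(m, w$layers)
  expect_equal(sum(p$farm_shares), 100, tolerance = 0.1)
})

test_that("resident and buffer populations come from disjoint cell sets and buffers grow", {
  w <- shared_world()
  b <- build_baseline(w$pa_records, w$grid, land = w$land)
  pops <- sapply(c(5, 10, 15), function(d)
    social_profile(b$mask, w$layers, buffer_km = d)$buffer_pop)
  expect_true(all(diff(pops) >= 0))
})

test_that("population scaling doubles counts and leaves shares and means unchanged", {
  lay <- hand_layers()
  g <- lay$population_t0$grid
  lay2 <- lay
  for (nm in c("population_t0", "population_t1", "wildharvest_pop"))
    lay2[[nm]] <- raster_layer(g, lay[[nm]]$values * 2, "count")
  m <- matrix(FALSE, 3, 3); m[1, ] <- TRUE; m[2, 2] <- TRUE
  p1 <- social_profile(cell_mask(g, m), lay)
  p2 <- social_profile(cell_mask(g, m), lay2)
  expect_equal(p2$resident_pop, 2 * p1$resident_pop)
  expect_equal(p2$buffer_pop, 2 * p1$buffer_pop)
  expect_equal(p2$hdi_category_pct, p1$hdi_category_pct)
  expect_equal(p2$mean_hdi, p1$mean_hdi)
  expect_equal(p2$wildharvest_share, p1$wildharvest_share)
  expect_equal(p2$farm_shares, p1$farm_shares)
  expect_equal(p2$growth_pct, p1$growth_pct)
})

test_that("continental rows partition the global profile", {
  lay <- hand_layers()
  g <- lay$population_t0$grid
  m <- matrix(FALSE, 3, 3); m[1, ] <- TRUE; m[2, 2] <- TRUE
  tab <- profile_by_continent(cell_mask(g, m), lay)
  expect_equal(sort(tab$continent), c("east", "west"))
  expect_equal(sum(tab$resident_pop),
               social_profile(cell_mask(g, m), lay)$resident_pop)
  # west: cells (1,1)=100 and (1,2)=200; east: (1,3)=0, (2,2)=400
  expect_equal(tab$resident_pop[tab$continent == "west"], 300)
  expect_equal(tab$mean_hdi[tab$continent == "west"],
               (0.54 * 100 + 0.55 * 200) / 300)
  # continental reference mean covers the whole continent, mask or not
  popw <- c(100, 200, 50)  # west cells (1,1),(1,2),(2,1) hold population
  expect_equal(tab$continental_mean_hdi[tab$continent == "west"],
               (0.54 * 100 + 0.55 * 200 + 0.80 * 50) / 350)
})

test_that("single-continent and empty-zone cases degrade gracefully", {
  g <- grid_spec(2, 2, 5)
  pop <- raster_layer(g, matrix(10, 2, 2), "count")
  hdi <- raster_layer(g, matrix(0.5, 2, 2), "continuous")
  zero <- raster_layer(g, matrix(0, 2, 2), "count")
  one <- raster_layer(g, matrix(1, 2, 2), "categorical")
  lay <- social_layers(pop, pop, hdi, zero, zero, zero, zero, one, 9,
                       tropics = empty_mask(g), continents = one,
                       land = full_mask(g))
  tab <- profile_by_continent(full_mask(g), lay)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$resident_pop, 40)

  tab2 <- profile_by_continent(empty_mask(g), lay)
  expect_equal(tab2$resident_pop, 0)
  expect_true(is.na(tab2$mean_hdi))
})

test_that("overlap analysis reduces correctly for identical and disjoint masks", {
  g <- grid_spec(4, 4, 5)
  a <- mask_from_cells(g, 1:4)
  land <- full_mask(g)
  base <- empty_mask(g)
  same <- overlap_analysis(list(bio = a, ncp = a, itt = a), land, base)
  expect_equal(same$unique_frac$unique_fraction, c(0, 0, 0))
  expect_equal(same$triple_share, 1)

  b <- mask_from_cells(g, 5:8); c3 <- mask_from_cells(g, 9:12)
  dis <- overlap_analysis(list(bio = a, ncp = b, itt = c3), land, base)
  expect_equal(dis$unique_frac$unique_fraction, c(1, 1, 1))
  expect_equal(dis$pairwise$jaccard, c(0, 0, 0))
  expect_equal(dis$triple_share, 0)
  expect_equal(dis$none_fraction, 4 / 16)
})

test_that("overlap fractions match set enumeration on a hand-drawn trio", {
  g <- grid_spec(4, 4, 5)
  a <- mask_from_cells(g, c(1, 2, 3, 4, 5))
  b <- mask_from_cells(g, c(4, 5, 6, 7))
  c3 <- mask_from_cells(g, c(5, 7, 8))
  base <- mask_from_cells(g, 16)
  ov <- overlap_analysis(list(bio = a, ncp = b, itt = c3), full_mask(g), base)
  expect_equal(ov$unique_frac$unique_fraction, c(3 / 5, 1 / 4, 1 / 3))
  ab <- ov$pairwise[ov$pairwise$a == "bio" & ov$pairwise$b == "ncp", ]
  expect_equal(ab$share_of_a, 2 / 5)
  expect_equal(ab$share_of_b, 2 / 4)
  expect_equal(ab$jaccard, 2 / 7)
  expect_equal(ov$triple_share, 1 / 8)  # {5} over union of 8 cells
  expect_equal(ov$none_fraction, (16 - 8 - 1) / 16)
  # masks must already exclude the baseline
  expect_error(overlap_analysis(list(bio = a, ncp = b, itt = base),
                                full_mask(g), base), "disjoint")
})

test_that("a no-op sensitivity sweep reproduces the single profile", {
  lay <- hand_layers()
  g <- lay$population_t0$grid
  m <- cell_mask(g, matrix(c(TRUE, TRUE, rep(FALSE, 7)), 3, 3))
  sw <- sensitivity_sweep(m, lay, alternates = list(), buffer_list = 10)
  expect_equal(nrow(sw), 1)
  ref <- profile_row(social_profile(m, lay, 10))
  expect_equal(sw$resident_pop, ref$resident_pop)
  expect_equal(sw$mean_hdi, ref$mean_hdi)
})

test_that("sensitivity sweeps vary buffers monotonically and scale with population", {
  lay <- hand_layers()
  g <- lay$population_t0$grid
  m <- cell_mask(g, matrix(c(TRUE, TRUE, rep(FALSE, 7)), 3, 3))
  pop2 <- raster_layer(g, lay$population_t0$values * 2, "count")
  sw <- sensitivity_sweep(m, lay,
                          alternates = list(double_pop = list(population_t0 = pop2)),
                          buffer_list = c(5, 10, 15))
  ref <- sw[sw$dataset == "reference", ]
  expect_true(all(diff(ref$buffer_pop[order(ref$buffer_km)]) >= 0))
  dbl <- sw[sw$dataset == "double_pop" & sw$buffer_km == 10, ]
  expect_equal(dbl$resident_pop, 2 * ref$resident_pop[ref$buffer_km == 10])
  expect_equal(dbl$pct_low, ref$pct_low[ref$buffer_km == 10])

  # an alternate on the wrong grid is skipped with a logged reason
  g2 <- grid_spec(2, 2, 5)
  bad <- raster_layer(g2, matrix(1, 2, 2), "count")
  expect_message(
    sw2 <- sensitivity_sweep(m, lay,
                             alternates = list(bad = list(population_t0 = bad)),
                             buffer_list = 10),
    "skipped")
  expect_false("bad" %in% sw2$dataset)
})
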