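# Seeded synthetic-world generator.
#
# Emulates the statistical structure of the global layers the analysis
# consumes -- clustered population, HDI spatially correlated with density,
# wild harvesting concentrated in the low-HDI tropics, low-modification
# remote land hosting Indigenous and community territories -- on a small
# planar equal-area grid, so the whole pipeline runs without any download.
# All randomness flows from one seed through named substreams (one
# `set.seed(seed + offset)` per component) so changing one component's draw
# count does not perturb the others.

substream <- c(land = 0L, population = 1L, hdi = 2L, hmi = 3L, iplc = 4L,
               icca = 5L, ncp = 6L, species = 7L, ecoregions = 8L, kbas = 9L,
               pa = 10L, continents = 11L, growth = 12L)

#' Synthetic-world configuration
#'
#' Defaults produce a 60 x 60 grid of 5 km cells (a 300 x 300 km world,
#' ~3,600 cells) in well under ten seconds. Latitude is synthesized as a
#' linear north-south coordinate spanning `lat_range`, so the tropics band
#' (|latitude| <= 24 degrees) covers a realistic share of rows without any
#' spherical geometry.
#'
#' @param n_rows,n_cols grid dimensions (default 60 x 60).
#' @param cell_size_km cell side (default 5 km, 25 km2 cells).
#' @param fine_factor fine-grid subdivision for the population raster
#'   (default 5, i.e. 1 km fine cells aggregated by summation).
#' @param land_fraction fraction of cells that are land (default 0.85).
#' @param n_population_clusters number of population centres (default 8).
#' @param cluster_meanlog,cluster_sdlog log-normal parameters of cluster
#'   population masses (defaults 11.5 and 0.8, mean ~ 1.4e5 persons).
#' @param cluster_sigma_km kernel scale of each centre (default 18 km).
#' @param background_density persons/km2 of diffuse rural background
#'   (default 1.5).
#' @param hdi_density_cor target correlation between HDI and log population
#'   density (default 0.8).
#' @param hdi_sd HDI spread per unit of the standardized driver; the driver
#'   is mapped linearly to `0.65 + hdi_sd * driver`, clipped to `[0.02, 0.98]`
#'   (default 0.14, giving all four HDI categories realistic mass).
#' @param wildharvest_base_rate share of households wild-harvesting at
#'   mid-range HDI (default 0.2, low enough that the rate stays below 1 even
#'   after a planted territory multiplier).
#' @param wildharvest_elasticity exponential decline of that rate with HDI
#'   (default 3).
#' @param hmi_density_scale persons/km2 at which modification saturates
#'   (default 25).
#' @param n_species,n_ecoregions,n_kbas feature counts (defaults 30, 8, 6).
#' @param aoh_range_km2 log-uniform range-size bounds for species areas of
#'   habitat (default c(200, 400000), capped at 60 percent of land).
#' @param ecoregion_target_fraction representation target used for the emitted
#'   ecoregion features (default 0.15).
#' @param n_iplc,iplc_meanlog,iplc_sdlog territory blob count and log-normal
#'   area parameters (defaults 12, log(4500), 0.45; sized so the union of
#'   territories, community conserved areas and the baseline comfortably
#'   exceeds the 30 percent coverage target before random trimming, as the
#'   territory scenario construction assumes).
#' @param n_icca community conserved-area records (default 5).
#' @param pa_count ordinary protected-area polygons (default 13; with
#'   `pa_meanlog` the implied baseline covers roughly a sixth of land).
#' @param pa_meanlog,pa_sdlog log-normal area parameters of those polygons
#'   (defaults log(1150), 0.4).
#' @param n_continents continent partition count (default 3).
#' @param lat_range latitude span of the grid rows (default c(-60, 60)).
#' @param seed integer master seed.
#' @return a list of class `world_config`.
#' @export
world_config <- function(n_rows = 60, n_cols = 60, cell_size_km = 5,
                         fine_factor = 5, land_fraction = 0.85,
                         n_population_clusters = 8,
                         cluster_meanlog = 11.5, cluster_sdlog = 0.8,
                         cluster_sigma_km = 18, background_density = 1.5,
                         hdi_density_cor = 0.8, hdi_sd = 0.14,
                         wildharvest_base_rate = 0.2,
                         wildharvest_elasticity = 3,
                         hmi_density_scale = 25,
                         n_species = 30, n_ecoregions = 8, n_kbas = 6,
                         aoh_range_km2 = c(200, 400000),
                         ecoregion_target_fraction = 0.15,
                         n_iplc = 12, iplc_meanlog = log(4500), iplc_sdlog = 0.45,
                         n_icca = 5,
                         pa_count = 13, pa_meanlog = log(1150), pa_sdlog = 0.4,
                         n_continents = 3, lat_range = c(-60, 60),
                         seed = 1L) {
  cfg <- as.list(environment())
  if (land_fraction <= 0 && n_population_clusters > 0)
    stop("infeasible config: no land but population clusters requested")
  if (land_fraction < 0 || land_fraction > 1) stop("land_fraction in [0,1]")
  if (hdi_density_cor < 0 || hdi_density_cor > 1) stop("hdi_density_cor in [0,1]")
  counts <- c(n_population_clusters, n_species, n_ecoregions, n_kbas, n_iplc,
              n_icca, pa_count, n_continents)
  if (any(counts < 0)) stop("counts must be >= 0")
  structure(cfg, class = "world_config")
}

# separable Gaussian smoothing of a matrix (reflecting edges via
# renormalized truncated kernels), used for all spatially correlated noise.
smooth_matrix <- function(z, sigma_cells) {
  n <- nrow(z); m <- ncol(z)
  kmat <- function(n) {
    d <- abs(outer(seq_len(n), seq_len(n), "-"))
    k <- exp(-d^2 / (2 * sigma_cells^2))
    k / rowSums(k)
  }
  kmat(n) %*% z %*% t(kmat(m))
}

smooth_noise <- function(n, m, sigma_cells) {
  s <- smooth_matrix(matrix(stats::rnorm(n * m), n, m), sigma_cells)
  (s - mean(s)) / stats::sd(s)
}

# share of households wild-harvesting as a function of HDI (capped at 1)
wildharvest_rate <- function(hdi, config) {
  pmin(config$wildharvest_base_rate *
         exp(-config$wildharvest_elasticity * (hdi - 0.5)), 1)
}

# n land cells nearest to a centre cell, as a logical matrix (geometric blob)
blob_cells <- function(grid, land, center_cell, n_cells) {
  cc <- cell_centers(grid)
  d2 <- (cc$x - cc$x[center_cell])^2 + (cc$y - cc$y[center_cell])^2
  d2[!land] <- Inf
  idx <- order(d2)[seq_len(min(n_cells, sum(land)))]
  out <- matrix(FALSE, grid$n_rows, grid$n_cols)
  out[idx] <- TRUE
  out
}

#' Generate a synthetic world
#'
#' Deterministic given `config$seed`. See [world_config()] for what each layer
#' emulates. The fine-grid population (factor `fine_factor`) is emitted
#' alongside its sum-aggregated coarse version so aggregation can be
#' exercised end-to-end.
#'
#' @param config a `world_config`.
#' @return a list of class `synthetic_world` with: `grid`, `land`, `layers`
#'   (a `social_layers` bundle), `population_fine` (fine-grid count layer),
#'   `hmi`, `ncp_rank`, `latitude` (per-row degrees), `features`
#'   (species + ecoregion `conservation_feature`s), `ecoregions`
#'   (categorical layer), `kbas` (`cell_mask`), `pa_records`, `iplc_lands`,
#'   `icca_records`, and `truth` (the planted parameters actually used).
#' @export
generate_world <- function(config = world_config()) {
  stopifnot(inherits(config, "world_config"))
  g <- grid_spec(config$n_rows, config$n_cols, config$cell_size_km)
  nr <- g$n_rows; nc <- g$n_cols; ca <- cell_area(g)
  seed <- config$seed
  truth <- list(config = config)

  # --- land: thresholded smooth field -> contiguous-ish continents
  set.seed(seed + substream[["land"]])
  lf <- smooth_noise(nr, nc, 6)
  land_mat <- lf >= stats::quantile(lf, 1 - config$land_fraction)
  if (config$land_fraction >= 1) land_mat[] <- TRUE
  land <- cell_mask(g, land_mat)

  # --- population on the fine grid (clusters + rural background)
  ff <- config$fine_factor
  fg <- grid_spec(nr * ff, nc * ff, g$cell_size_km / ff)
  set.seed(seed + substream[["population"]])
  land_cells <- which(land_mat)
  ncl <- min(config$n_population_clusters, length(land_cells))
  centers <- if (ncl > 0) sample(land_cells, ncl) else integer(0)
  masses <- stats::rlnorm(ncl, config$cluster_meanlog, config$cluster_sdlog)
  fcc <- cell_centers(fg)
  fine_land <- land_mat[rep(seq_len(nr), each = ff), rep(seq_len(nc), each = ff)]
  dens_f <- matrix(0, fg$n_rows, fg$n_cols)
  cc <- cell_centers(g)
  for (k in seq_len(ncl)) {
    d2 <- (fcc$x - cc$x[centers[k]])^2 + (fcc$y - cc$y[centers[k]])^2
    kern <- exp(-d2 / (2 * config$cluster_sigma_km^2))
    kern[!fine_land] <- 0
    s <- sum(kern)
    if (s > 0) dens_f <- dens_f + masses[k] * kern / s
  }
  dens_f <- dens_f + config$background_density * cell_area(fg) *
    fine_land * (0.5 + stats::runif(fg$n_rows * fg$n_cols))
  dens_f[!fine_land] <- NA
  population_fine <- raster_layer(fg, dens_f, "count")
  population_t0 <- regrid(population_fine, ff, "sum")
  population_t0$values[!land_mat] <- NA
  pop0 <- population_t0$values

  # --- HDI: logistic of (rho * standardized log density + noise)
  set.seed(seed + substream[["hdi"]])
  ldens <- log1p(ifelse(is.na(pop0), 0, pop0) / ca)
  zl <- (ldens - mean(ldens[land_mat])) / stats::sd(ldens[land_mat])
  rho <- config$hdi_density_cor
  noise <- smooth_noise(nr, nc, 4)
  raw <- rho * zl + sqrt(1 - rho^2) * noise
  hdi_v <- pmin(pmax(0.65 + config$hdi_sd * raw, 0.02), 0.98)
  hdi_v[!land_mat] <- NA
  hdi <- raster_layer(g, hdi_v, "continuous")

  # --- HMI: saturating in population density, small smooth noise
  set.seed(seed + substream[["hmi"]])
  dens <- ifelse(is.na(pop0), 0, pop0) / ca
  hmi_v <- 1 - exp(-dens / config$hmi_density_scale)
  hmi_v <- pmin(pmax(hmi_v + 0.04 * smooth_noise(nr, nc, 3), 0), 1)
  hmi_v[!land_mat] <- NA
  hmi <- raster_layer(g, hmi_v, "continuous")

  # --- latitude rows and tropics band
  lat <- seq(config$lat_range[1], config$lat_range[2], length.out = nr + 1)
  lat <- (lat[-1] + lat[-(nr + 1)]) / 2  # row-centre latitudes
  tropics_mat <- matrix(abs(lat) <= 24, nr, nc)
  tropics <- cell_mask(g, tropics_mat)

  # --- wild harvesting: population x rate(HDI) inside the tropics
  rate <- wildharvest_rate(hdi_v, config)
  wh_v <- ifelse(tropics_mat & land_mat, pop0 * rate, 0)
  wh_v[!land_mat] <- NA
  wildharvest <- raster_layer(g, wh_v, "count")

  # --- territories: blobs seeded preferentially where modification is low
  set.seed(seed + substream[["iplc"]])
  hdi_med <- stats::median(hdi_v[land_mat], na.rm = TRUE)
  low_hmi <- land_mat & !is.na(hmi_v) & hmi_v <= 0.1
  w_ip <- ifelse(low_hmi & !is.na(hdi_v) & hdi_v <= hdi_med, 1,
                 ifelse(low_hmi, 0.15, 0))
  w_ip <- w_ip * ifelse(tropics_mat, 2, 1)  # custodian lands mostly tropical
  if (sum(w_ip) == 0) w_ip <- land_mat * 1  # degenerate world: no intact land
  iplc_lands <- list()
  if (config$n_iplc > 0) {
    ctr <- sample(seq_along(w_ip), config$n_iplc, prob = w_ip)
    areas <- stats::rlnorm(config$n_iplc, config$iplc_meanlog, config$iplc_sdlog)
    flags <- c("subject_to_other_special_rights",
               rep("none", config$n_iplc - 1))  # first blob carries the flag
    iplc_lands <- lapply(seq_len(config$n_iplc), function(k)
      list(geometry = geom_circle(cc$x[ctr[k]], cc$y[ctr[k]], areas[k],
                                  id = sprintf("iplc_%02d", k)),
           rights_flag = flags[k]))
    truth$iplc_centers <- ctr
    truth$iplc_areas <- areas
  }

  # --- community conserved areas: small records, some point-format
  set.seed(seed + substream[["icca"]])
  icca_records <- list()
  if (config$n_icca > 0) {
    ctr <- sample(seq_along(w_ip), config$n_icca, prob = w_ip)
    areas <- stats::runif(config$n_icca, 200, 800)
    icca_records <- lapply(seq_len(config$n_icca), function(k) {
      id <- sprintf("icca_%02d", k)
      if (k %% 2 == 0)  # even records arrive as points with a reported area
        pa_record(id, "established", "OECM",
                  geom_point(cc$x[ctr[k]], cc$y[ctr[k]], id = id),
                  reported_area_km2 = areas[k])
      else
        pa_record(id, "established", "OECM",
                  geom_circle(cc$x[ctr[k]], cc$y[ctr[k]], areas[k], id = id),
                  reported_area_km2 = areas[k])
    })
  }

  # --- NCP priority: realized services = intact (low-HMI) supply weighted by
  # beneficiaries within reach, so priorities sit near but not inside the
  # densest areas, plus smooth noise
  set.seed(seed + substream[["ncp"]])
  supply <- smooth_matrix(ifelse(land_mat, 1 - ifelse(is.na(hmi_v), 0.5, hmi_v), 0), 3)
  demand <- smooth_matrix(ifelse(land_mat, log1p(ifelse(is.na(pop0), 0, pop0) / ca), 0), 8)
  demand <- demand / max(demand)
  ncp_v <- supply * (0.15 + 0.85 * demand) + 0.08 * smooth_noise(nr, nc, 3)
  ncp_v <- ncp_v - min(ncp_v)  # non-negative so value shares are meaningful
  ncp_v[!land_mat] <- NA
  ncp_rank <- raster_layer(g, ncp_v, "continuous")

  # --- species areas of habitat: geometric ranges, log-uniform size
  set.seed(seed + substream[["species"]])
  n_land <- sum(land_mat)
  amax <- min(config$aoh_range_km2[2], 0.6 * n_land * ca)
  features <- list()
  for (s in seq_len(config$n_species)) {
    a <- exp(stats::runif(1, log(config$aoh_range_km2[1]), log(amax)))
    ctr <- sample(land_cells, 1)
    blob <- blob_cells(g, land_mat, ctr, max(1, round(a / ca)))
    amt <- raster_layer(g, blob * ca, "count")
    tot <- sum(blob) * ca
    features[[length(features) + 1]] <- conservation_feature(
      sprintf("sp_%03d", s), "species", amt, species_target(tot) * tot)
  }

  # --- ecoregions: seeded Voronoi partition of land
  set.seed(seed + substream[["ecoregions"]])
  eco_v <- matrix(NA_real_, nr, nc)
  if (config$n_ecoregions > 0 && n_land > 0) {
    ctr <- sample(land_cells, min(config$n_ecoregions, n_land))
    d2 <- sapply(ctr, function(cl) (cc$x - cc$x[cl])^2 + (cc$y - cc$y[cl])^2)
    eco_v[land_cells] <- apply(d2[land_cells, , drop = FALSE], 1, which.min)
    for (e in sort(unique(eco_v[land_cells]))) {
      blob <- !is.na(eco_v) & eco_v == e
      amt <- raster_layer(g, blob * ca, "count")
      features[[length(features) + 1]] <- conservation_feature(
        sprintf("eco_%02d", e), "ecoregion", amt,
        config$ecoregion_target_fraction * sum(blob) * ca)
    }
  }
  ecoregions <- raster_layer(g, eco_v, "categorical")

  # --- key biodiversity areas: small blobs
  set.seed(seed + substream[["kbas"]])
  kba_mat <- matrix(FALSE, nr, nc)
  if (config$n_kbas > 0 && n_land > 0) {
    ctr <- sample(land_cells, config$n_kbas)
    sizes <- sample(5:20, config$n_kbas, replace = TRUE)
    for (k in seq_len(config$n_kbas))
      kba_mat <- kba_mat | blob_cells(g, land_mat, ctr[k], sizes[k])
  }
  kbas <- cell_mask(g, kba_mat)

  # --- protected-area records, including the tricky register fixtures
  set.seed(seed + substream[["pa"]])
  pa_records <- list()
  if (config$pa_count > 0 && n_land > 0) {
    # protected areas sit mostly outside the intact territory heartlands
    ctr <- sample(land_cells, config$pa_count, prob = 1 / (1 + 4 * w_ip[land_cells]))
    areas <- stats::rlnorm(config$pa_count, config$pa_meanlog, config$pa_sdlog)
    pa_records <- lapply(seq_len(config$pa_count), function(k) {
      id <- sprintf("pa_%03d", k)
      asp <- stats::runif(1, 0.6, 1.6)
      w <- sqrt(areas[k] * asp); h <- areas[k] / w
      pa_record(id, "designated", "PA",
                geom_rect(cc$x[ctr[k]] - w / 2, cc$y[ctr[k]] - h / 2,
                          cc$x[ctr[k]] + w / 2, cc$y[ctr[k]] + h / 2, id = id),
                reported_area_km2 = areas[k])
    })
  }
  # fixtures exercising every filtering rule
  ocean_cells <- which(!land_mat)
  fix_ctr <- c(sample(land_cells, 4),
               if (length(ocean_cells)) sample(ocean_cells, 1) else sample(land_cells, 1))
  mk_sq <- function(cell, a, id) {
    s <- sqrt(a)
    geom_rect(cc$x[cell] - s / 2, cc$y[cell] - s / 2,
              cc$x[cell] + s / 2, cc$y[cell] + s / 2, id = id)
  }
  pa_records <- c(pa_records, list(
    pa_record("fix_proposed", "proposed", "PA", mk_sq(fix_ctr[1], 400, "fix_proposed"),
              reported_area_km2 = 400),
    pa_record("fix_mab", "designated", "PA", mk_sq(fix_ctr[2], 400, "fix_mab"),
              designation_flag = "MAB_biosphere", reported_area_km2 = 400),
    pa_record("fix_point_area", "designated", "PA",
              geom_point(cc$x[fix_ctr[3]], cc$y[fix_ctr[3]], id = "fix_point_area"),
              reported_area_km2 = 150),
    pa_record("fix_point_noarea", "designated", "PA",
              geom_point(cc$x[fix_ctr[4]], cc$y[fix_ctr[4]], id = "fix_point_noarea")),
    pa_record("fix_marine", "designated", "PA", mk_sq(fix_ctr[5], 400, "fix_marine"),
              realm = "marine", reported_area_km2 = 400)))

  # --- continents: Voronoi partition of the grid, reported on land
  set.seed(seed + substream[["continents"]])
  cont_v <- matrix(NA_real_, nr, nc)
  if (config$n_continents > 0 && n_land > 0) {
    ctr <- sample(land_cells, min(config$n_continents, n_land))
    d2 <- sapply(ctr, function(cl) (cc$x - cc$x[cl])^2 + (cc$y - cc$y[cl])^2)
    cont_v[land_cells] <- apply(d2[land_cells, , drop = FALSE], 1, which.min)
  }
  continents <- raster_layer(g, cont_v, "categorical")

  # --- growth to the second epoch: faster where HDI is low
  set.seed(seed + substream[["growth"]])
  grate <- pmax(0.30 * (1 - ifelse(is.na(hdi_v), 0.7, hdi_v)) +
                  0.02 * smooth_noise(nr, nc, 4), 0)
  p1 <- pop0 * (1 + grate)
  p1[!land_mat] <- NA
  population_t1 <- raster_layer(g, p1, "count")

  # --- livelihood area layers: farm classes tile the cell, rangeland code
  dshare <- dens / (dens + 20)                      # farmed fraction of cell
  f_farm <- pmin(dshare, 0.85)
  small_share <- pmin(pmax(1.2 - hdi_v * 1.4, 0), 1)  # small farms where HDI low
  small_share[is.na(small_share)] <- 0
  farm_small <- raster_layer(g, ifelse(land_mat, ca * f_farm * small_share, NA), "count")
  farm_large <- raster_layer(g, ifelse(land_mat, ca * f_farm * (1 - small_share), NA), "count")
  farm_nonf <- raster_layer(g, ifelse(land_mat, ca * (1 - f_farm), NA), "count")
  ls_v <- matrix(NA_real_, nr, nc)
  ls_v[land_mat] <- 0
  ls_v[land_mat & f_farm < 0.2 & dens > 0.5] <- 1   # livestock-only rangeland
  ls_v[land_mat & f_farm >= 0.2 & f_farm < 0.5] <- 2  # mixed rainfed
  ls_v[land_mat & f_farm >= 0.5] <- 3               # mixed irrigated
  livestock <- raster_layer(g, ls_v, "categorical")

  layers <- social_layers(
    population_t0 = population_t0, population_t1 = population_t1,
    hdi = hdi, wildharvest_pop = wildharvest,
    farm_nonfarmed = farm_nonf, farm_small = farm_small, farm_large = farm_large,
    livestock_system = livestock, livestock_only_code = 1,
    tropics = tropics, continents = continents,
    continent_names = stats::setNames(paste0("continent_", seq_len(config$n_continents)),
                                      seq_len(config$n_continents)),
    land = land)

  structure(list(grid = g, land = land, layers = layers,
                 population_fine = population_fine,
                 hmi = hmi, ncp_rank = ncp_rank, latitude = lat,
                 features = features, ecoregions = ecoregions, kbas = kbas,
                 pa_records = pa_records, iplc_lands = iplc_lands,
                 icca_records = icca_records, truth = truth),
            class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf("<synthetic_world> %d x %d cells, %d land (%.0f%%), %d features, %d PA records, %d territories\n",
              x$grid$n_rows, x$grid$n_cols, mask_cells(x$land),
              100 * mask_cells(x$land) / (x$grid$n_rows * x$grid$n_cols),
              length(x$features), length(x$pa_records), length(x$iplc_lands)))
  invisible(x)
}

#' Plant a social contrast inside the territory lands
#'
#' Lowers HDI and raises wild-harvest rates inside the (non-excluded)
#' territory and community conserved-area geometries by the stated amounts, so the profiler's qualitative
#' recovery of the territories scenario's social signature can be tested
#' against a known planted truth. HDI values falling outside `[0, 1]` are
#' clipped, with the clip count recorded in `truth`.
#'
#' @param world a `synthetic_world`.
#' @param iplc_hdi_offset additive HDI change inside territories
#'   (default -0.2).
#' @param iplc_wildharvest_multiplier multiplier on wild-harvest population
#'   inside territories, capped at the total population (default 2).
#' @return the modified `synthetic_world` (with `truth$contrast` set).
#' @export
plant_contrast <- function(world, iplc_hdi_offset = -0.2,
                           iplc_wildharvest_multiplier = 2) {
  stopifnot(inherits(world, "synthetic_world"))
  keep <- vapply(world$iplc_lands, function(e)
    !identical(e$rights_flag, "subject_to_other_special_rights"), TRUE)
  terr_geoms <- lapply(world$iplc_lands[keep], function(e) e$geometry)
  icca_geoms <- filter_records(world$icca_records)$geoms
  geoms <- c(terr_geoms, icca_geoms)
  if (!length(geoms) || (iplc_hdi_offset == 0 && iplc_wildharvest_multiplier == 1)) {
    world$truth$contrast <- list(offset = iplc_hdi_offset,
                                 multiplier = iplc_wildharvest_multiplier,
                                 cells = 0L, clipped = 0L)
    return(world)
  }
  # the contrast is planted in the intact (low-modification) parts of the
  # broad territory polygons -- the custodian heartlands, not their settled
  # fringes -- and throughout the community conserved areas, which are
  # custodian-governed in full
  intact <- !is.na(world$hmi$values) & world$hmi$values <= 0.1
  inside_terr <- if (length(terr_geoms))
    rasterize_coverage(terr_geoms, world$grid)$values >= 0.5 & intact
    else matrix(FALSE, world$grid$n_rows, world$grid$n_cols)
  inside_icca <- if (length(icca_geoms))
    rasterize_coverage(icca_geoms, world$grid)$values >= 0.5
    else matrix(FALSE, world$grid$n_rows, world$grid$n_cols)
  inside <- (inside_terr | inside_icca) & world$land$included

  hdi <- world$layers$hdi$values
  new_hdi <- hdi
  new_hdi[inside] <- hdi[inside] + iplc_hdi_offset
  clipped <- sum(new_hdi < 0 | new_hdi > 1, na.rm = TRUE)
  if (clipped > 0) warning("plant_contrast: ", clipped, " HDI value(s) clipped to [0, 1]")
  new_hdi <- pmin(pmax(new_hdi, 0), 1)
  world$layers$hdi <- raster_layer(world$grid, new_hdi, "continuous")

  # the wild-harvest rate is re-derived from the lowered HDI before the
  # territory multiplier, so the planted poverty and livelihood signals agree
  wh <- world$layers$wildharvest_pop$values
  pop <- world$layers$population_t0$values
  trop <- world$layers$tropics$included
  cfgw <- world$truth$config
  sel <- inside & trop & !is.na(pop)
  wh[sel] <- pmin(pop[sel] * wildharvest_rate(new_hdi[sel], cfgw) *
                    iplc_wildharvest_multiplier, pop[sel])
  world$layers$wildharvest_pop <- raster_layer(world$grid, wh, "count")

  world$truth$contrast <- list(offset = iplc_hdi_offset,
                               multiplier = iplc_wildharvest_multiplier,
                               cells = sum(inside, na.rm = TRUE),
                               clipped = clipped)
  world
}
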