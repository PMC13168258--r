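#' Bundle the social layers used by the profiler
#'
#' All layers must share one grid. Farm components are per-cell areas (km2)
#' and may not exceed the cell area in total; wild-harvest population is only
#' defined inside the tropics band and may not exceed total population there.
#'
#' @param population_t0,population_t1 count `raster_layer`s (persons) for the
#'   two population epochs (current and projected).
#' @param hdi continuous `raster_layer` in `[0, 1]`.
#' @param wildharvest_pop count `raster_layer`, persons in wild-harvesting
#'   households (tropics only, 0/nodata elsewhere).
#' @param farm_nonfarmed,farm_small,farm_large count `raster_layer`s of km2
#'   per cell in each farm-size class (small = up to 5 ha, large = over 5 ha).
#' @param livestock_system categorical `raster_layer` of production systems.
#' @param livestock_only_code category code of "livestock only" systems.
#' @param tropics `cell_mask` of the tropical band (|latitude| <= 24 degrees).
#' @param continents categorical `raster_layer` of continent codes.
#' @param continent_names optional named character vector mapping codes to
#'   names.
#' @param land land `cell_mask`.
#' @return a list of class `social_layers`.
#' @export
social_layers <- function(population_t0, population_t1, hdi, wildharvest_pop,
                          farm_nonfarmed, farm_small, farm_large,
                          livestock_system, livestock_only_code,
                          tropics, continents, continent_names = NULL, land) {
  layers <- list(population_t0 = population_t0, population_t1 = population_t1,
                 hdi = hdi, wildharvest_pop = wildharvest_pop,
                 farm_nonfarmed = farm_nonfarmed, farm_small = farm_small,
                 farm_large = farm_large, livestock_system = livestock_system,
                 continents = continents)
  g <- population_t0$grid
  for (nm in names(layers)) check_same_grid(layers[[nm]]$grid, g, nm)
  check_same_grid(tropics$grid, g, "tropics")
  check_same_grid(land$grid, g, "land")
  ca <- cell_area(g)
  farm_tot <- farm_nonfarmed$values + farm_small$values + farm_large$values
  if (any(farm_tot > ca + 1e-6, na.rm = TRUE))
    stop("farm area components exceed cell area in some cells")
  wh <- wildharvest_pop$values; p0 <- population_t0$values
  bad <- tropics$included & !is.na(wh) & !is.na(p0) & wh > p0 + 1e-6
  if (any(bad)) stop("wild-harvest population exceeds total population in tropics")
  structure(c(layers, list(livestock_only_code = livestock_only_code,
                           tropics = tropics,
                           continent_names = continent_names, land = land)),
            class = "social_layers")
}

# HDI class of each cell by the UNDP-style cutoffs, half-open so every value
# lands in exactly one class: [0,0.55) low, [0.55,0.70) medium,
# [0.70,0.80) high, [0.80,1] very high.
hdi_breaks <- c(0, 0.55, 0.70, 0.80)
hdi_levels <- c("low", "medium", "high", "very_high")

hdi_class <- function(hdi_values) {
  cls <- matrix(NA_integer_, nrow(hdi_values), ncol(hdi_values))
  ok <- !is.na(hdi_values)
  cls[ok] <- findInterval(hdi_values[ok], hdi_breaks)
  cls
}

#' Social profile of a mask
#'
#' Computes every per-mask social statistic reported by the analysis:
#' resident and 10 km-ring populations, population by Human Development Index
#' category, population-weighted mean HDI, wild-harvesting share of the
#' tropical resident population, farm-area shares, livestock-rangeland share,
#' and population growth between the two epochs.
#'
#' @param mask a `cell_mask` (a scenario, its new areas, or the baseline).
#' @param layers a `social_layers` bundle on the same grid.
#' @param buffer_km ring distance in km (default 10).
#' @return a list of class `social_profile`; population shares are
#'   percentages. `wildharvest_share` and `growth_pct` are `NA` when their
#'   denominator population is zero.
#' @export
social_profile <- function(mask, layers, buffer_km = 10) {
  stopifnot(inherits(layers, "social_layers"))
  check_same_grid(mask$grid, layers$population_t0$grid, "mask and layers")
  pop <- layers$population_t0
  resident_pop <- zonal_sum(pop, mask)
  ring <- buffer_mask(mask, buffer_km)
  buffer_pop <- zonal_sum(pop, ring)

  cls <- hdi_class(layers$hdi$values)
  cat_pops <- vapply(1:4, function(k) {
    sel <- mask$included & !is.na(cls) & cls == k
    sum(pop$values[sel], na.rm = TRUE)
  }, 0)
  names(cat_pops) <- hdi_levels
  pop_with_hdi <- sum(cat_pops)
  cat_pct <- if (pop_with_hdi > 0) 100 * cat_pops / pop_with_hdi else
    stats::setNames(rep(NA_real_, 4), hdi_levels)
  mean_hdi <- suppressWarnings(zonal_weighted_mean(layers$hdi, pop, mask))

  trop_mask <- mask_intersect(mask, layers$tropics)
  trop_pop <- zonal_sum(pop, trop_mask)
  wildharvest_share <- if (trop_pop > 0)
    100 * zonal_sum(layers$wildharvest_pop, trop_mask) / trop_pop else NA_real_

  area <- mask_area(mask)
  farm_shares <- if (area > 0) c(
    non_farmed = 100 * zonal_sum(layers$farm_nonfarmed, mask) / area,
    small = 100 * zonal_sum(layers$farm_small, mask) / area,
    large = 100 * zonal_sum(layers$farm_large, mask) / area
  ) else c(non_farmed = NA_real_, small = NA_real_, large = NA_real_)

  ls <- layers$livestock_system$values
  rangeland_share <- if (mask_cells(mask) > 0)
    100 * sum(mask$included & !is.na(ls) & ls == layers$livestock_only_code) /
      mask_cells(mask) else NA_real_

  p1 <- zonal_sum(layers$population_t1, mask)
  growth_pct <- if (resident_pop > 0) 100 * (p1 - resident_pop) / resident_pop
    else NA_real_

  structure(list(resident_pop = resident_pop, buffer_pop = buffer_pop,
                 buffer_km = buffer_km,
                 hdi_category_pops = cat_pops, hdi_category_pct = cat_pct,
                 mean_hdi = mean_hdi,
                 tropical_resident_pop = trop_pop,
                 wildharvest_share = wildharvest_share,
                 farm_shares = farm_shares,
                 rangeland_share = rangeland_share,
                 growth_pct = growth_pct),
            class = "social_profile")
}

#' @export
print.social_profile <- function(x, ...) {
  cat("<social_profile>\n")
  cat(sprintf("  residents %.5g; within %g km: %.5g; growth %+.1f%%\n",
              x$resident_pop, x$buffer_km, x$buffer_pop, x$growth_pct))
  cat(sprintf("  HDI mix (%%): low %.1f, medium %.1f, high %.1f, very high %.1f; mean HDI %.3f\n",
              x$hdi_category_pct[1], x$hdi_category_pct[2],
              x$hdi_category_pct[3], x$hdi_category_pct[4], x$mean_hdi))
  cat(sprintf("  wild harvesting %.1f%% of %.5g tropical residents\n",
              x$wildharvest_share, x$tropical_resident_pop))
  cat(sprintf("  area: non-farmed %.1f%%, small farms %.1f%%, large farms %.1f%%, rangeland %.1f%%\n",
              x$farm_shares[1], x$farm_shares[2], x$farm_shares[3],
              x$rangeland_share))
  invisible(x)
}

#' Flatten a social profile to a one-row data frame
#' @param p a `social_profile`.
#' @export
profile_row <- function(p) {
  data.frame(resident_pop = p$resident_pop, buffer_pop = p$buffer_pop,
             buffer_km = p$buffer_km,
             pop_low = p$hdi_category_pops[["low"]],
             pop_medium = p$hdi_category_pops[["medium"]],
             pop_high = p$hdi_category_pops[["high"]],
             pop_very_high = p$hdi_category_pops[["very_high"]],
             pct_low = p$hdi_category_pct[["low"]],
             pct_medium = p$hdi_category_pct[["medium"]],
             pct_high = p$hdi_category_pct[["high"]],
             pct_very_high = p$hdi_category_pct[["very_high"]],
             mean_hdi = p$mean_hdi,
             tropical_resident_pop = p$tropical_resident_pop,
             wildharvest_share = p$wildharvest_share,
             farm_non_farmed = p$farm_shares[["non_farmed"]],
             farm_small = p$farm_shares[["small"]],
             farm_large = p$farm_shares[["large"]],
             rangeland_share = p$rangeland_share,
             growth_pct = p$growth_pct)
}

#' Replicate-averaged social profile of a stochastic scenario
#'
#' Profiles each replicate mask of a territories-style scenario and averages
#' every numeric field across replicates.
#'
#' @param scenario a `scenario_result` with `replicate_masks`.
#' @param layers a `social_layers` bundle.
#' @param buffer_km ring distance (default 10).
#' @return list with `mean` (one-row data.frame of replicate means), `sd`
#'   (replicate standard deviations) and `per_replicate` (long data.frame).
#' @export
profile_replicates <- function(scenario, layers, buffer_km = 10) {
  reps <- scenario$replicate_masks
  if (is.null(reps)) stop("scenario has no stored replicate masks")
  g <- scenario$mask$grid
  rows <- do.call(rbind, lapply(seq_along(reps), function(r) {
    p <- profile_row(social_profile(cell_mask(g, reps[[r]]), layers, buffer_km))
    cbind(replicate = r, p)
  }))
  num <- rows[, setdiff(names(rows), "replicate")]
  list(mean = as.data.frame(as.list(colMeans(num))),
       sd = as.data.frame(as.list(apply(num, 2, stats::sd))),
       per_replicate = rows)
}

#' Per-continent social profile
#'
#' Profiles the intersection of a mask with each continent and reports the
#' continental population-weighted mean HDI as reference. Mask cells with a
#' missing continent code go to an "unassigned" row.
#'
#' @param mask a `cell_mask`.
#' @param layers a `social_layers` bundle (with `continents`).
#' @return data.frame with one row per continent: continent, resident_pop,
#'   mean_hdi (of mask residents; `NA` when the mask holds no population
#'   there), continental_mean_hdi (all residents of the continent).
#' @export
profile_by_continent <- function(mask, layers) {
  cont <- layers$continents$values
  codes <- sort(unique(cont[!is.na(cont)]))
  g <- mask$grid
  one <- function(sel_cont, label) {
    cmask <- cell_mask(g, sel_cont)
    sub <- mask_intersect(mask, cmask)
    rp <- zonal_sum(layers$population_t0, sub)
    mh <- if (rp > 0)
      suppressWarnings(zonal_weighted_mean(layers$hdi, layers$population_t0, sub))
      else NA_real_
    ch <- suppressWarnings(
      zonal_weighted_mean(layers$hdi, layers$population_t0, cmask))
    data.frame(continent = label, resident_pop = rp, mean_hdi = mh,
               continental_mean_hdi = ch, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(codes, function(cc) {
    label <- if (!is.null(layers$continent_names) &&
                 as.character(cc) %in% names(layers$continent_names))
      layers$continent_names[[as.character(cc)]] else as.character(cc)
    one(!is.na(cont) & cont == cc, label)
  }))
  if (any(mask$included & is.na(cont)))
    out <- rbind(out, one(is.na(cont), "unassigned"))
  rownames(out) <- NULL
  out
}

#' Overlap structure of the three scenarios' new areas
#'
#' Takes the scenarios' *new* cells (baseline subtracted by the caller) and
#' reports: each scenario's unique fraction, directional pairwise overlaps
#' |A&B|/|A| in both orders plus the symmetric Jaccard |A&B|/|A|B|, the
#' fraction of the union of all new cells shared by all three, and the
#' fraction of land in no scenario and not in the baseline.
#'
#' @param new_masks named list of three `cell_mask`s of new cells (names used
#'   in the report).
#' @param land land `cell_mask`.
#' @param baseline baseline `cell_mask` (new masks must be disjoint from it).
#' @return a list of class `overlap_report` with data.frames `unique_frac`,
#'   `pairwise`, and scalars `triple_share`, `none_fraction`.
#' @export
overlap_analysis <- function(new_masks, land, baseline) {
  stopifnot(length(new_masks) == 3)
  nms <- names(new_masks)
  base <- as_mask(baseline)
  for (nm in nms)
    if (mask_cells(mask_intersect(new_masks[[nm]], base)) > 0)
      stop("mask '", nm, "' is not disjoint from the baseline; subtract it first")
  m <- lapply(new_masks, function(x) x$included)
  sz <- vapply(m, sum, 0)
  uniq <- vapply(seq_along(m), function(i) {
    others <- Reduce(`|`, m[-i])
    if (sz[i] == 0) NA_real_ else sum(m[[i]] & !others) / sz[i]
  }, 0)
  pairs <- utils::combn(3, 2)
  pw <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    inter <- sum(m[[i]] & m[[j]]); uni <- sum(m[[i]] | m[[j]])
    data.frame(a = nms[i], b = nms[j],
               share_of_a = if (sz[i] > 0) inter / sz[i] else NA_real_,
               share_of_b = if (sz[j] > 0) inter / sz[j] else NA_real_,
               jaccard = if (uni > 0) inter / uni else NA_real_,
               stringsAsFactors = FALSE)
  }))
  all_new <- Reduce(`|`, m)
  triple <- if (sum(all_new) > 0) sum(m[[1]] & m[[2]] & m[[3]]) / sum(all_new)
    else NA_real_
  none <- sum(land$included & !all_new & !base$included) / mask_cells(land)
  structure(list(unique_frac = data.frame(scenario = nms, unique_fraction = uniq,
                                          stringsAsFactors = FALSE),
                 pairwise = pw, triple_share = triple, none_fraction = none),
            class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat("<overlap_report>\n  unique fractions:\n")
  for (k in seq_len(nrow(x$unique_frac)))
    cat(sprintf("    %s: %.1f%%\n", x$unique_frac$scenario[k],
                100 * x$unique_frac$unique_fraction[k]))
  cat("  pairwise (share of a / share of b / jaccard):\n")
  for (k in seq_len(nrow(x$pairwise)))
    cat(sprintf("    %s-%s: %.1f%% / %.1f%% / %.1f%%\n",
                x$pairwise$a[k], x$pairwise$b[k], 100 * x$pairwise$share_of_a[k],
                100 * x$pairwise$share_of_b[k], 100 * x$pairwise$jaccard[k]))
  cat(sprintf("  shared by all three: %.1f%% of new cells; %.1f%% of land in no scenario\n",
              100 * x$triple_share, 100 * x$none_fraction))
  invisible(x)
}

#' Sensitivity sweep over alternate layers and buffer distances
#'
#' Re-profiles each mask for every combination of a layer substitution set and
#' a buffer distance. A substitution set is a named list of replacement
#' `raster_layer`s (names matching `social_layers` fields); a set whose layers
#' are not on the common grid is skipped with a logged reason.
#'
#' @param masks named list of `cell_mask`s (one per scenario), or a single
#'   `cell_mask`.
#' @param layers the reference `social_layers`.
#' @param alternates named list of substitution sets; the reference layers are
#'   always included under the name "reference".
#' @param buffer_list numeric vector of buffer distances in km (default 10).
#' @return long data.frame keyed by scenario, dataset and buffer_km, one
#'   profile per row; skipped combinations are recorded in the "skipped"
#'   attribute.
#' @export
sensitivity_sweep <- function(masks, layers, alternates = list(),
                              buffer_list = 10) {
  if (inherits(masks, "cell_mask")) masks <- list(scenario = masks)
  g <- layers$population_t0$grid
  sets <- c(list(reference = list()), alternates)
  skipped <- character(0)
  out <- list()
  for (ds in names(sets)) {
    lay <- layers
    ok <- TRUE
    for (nm in names(sets[[ds]])) {
      sub <- sets[[ds]][[nm]]
      if (!same_grid(sub$grid, g)) {
        skipped <- c(skipped, sprintf("%s: layer '%s' not on the common grid", ds, nm))
        ok <- FALSE
        break
      }
      lay[[nm]] <- sub
    }
    if (!ok) next
    for (b in buffer_list) for (sc in names(masks)) {
      out[[length(out) + 1]] <- cbind(
        scenario = sc, dataset = ds,
        profile_row(social_profile(masks[[sc]], lay, buffer_km = b)))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if (length(skipped)) {
    for (s in skipped) message("sensitivity_sweep: skipped ", s)
    attr(res, "skipped") <- skipped
  }
  res
}
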