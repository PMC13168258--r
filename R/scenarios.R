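#' Scenario configuration
#'
#' Shared knobs of the three 30x30 expansion scenario builders.
#'
#' @param total_target_fraction total coverage target as a fraction of land
#'   (default 0.30, the Target 3 ambition).
#' @param ecoregion_target_fraction representation target for each ecoregion
#'   as a fraction of its area (default 0.15).
#' @param hmi_threshold Human Modification Index cutoff above which candidate
#'   cells are considered too modified for the territories scenario
#'   (default 0.1).
#' @param replicates number of random-removal replicates for the territories
#'   scenario (default 100).
#' @param seed integer seed; replicate r draws from `seed + r`.
#' @param tie_break tie-breaking rule; only "row_major" is defined.
#' @return a list of class `scenario_config`.
#' @export
scenario_config <- function(total_target_fraction = 0.30,
                            ecoregion_target_fraction = 0.15,
                            hmi_threshold = 0.1,
                            replicates = 100L,
                            seed = 1L,
                            tie_break = "row_major") {
  if (total_target_fraction <= 0 || total_target_fraction > 1)
    stop("total_target_fraction must lie in (0, 1]")
  tie_break <- match.arg(tie_break, "row_major")
  structure(list(total_target_fraction = total_target_fraction,
                 ecoregion_target_fraction = ecoregion_target_fraction,
                 hmi_threshold = hmi_threshold,
                 replicates = as.integer(replicates),
                 seed = as.integer(seed),
                 tie_break = tie_break),
            class = "scenario_config")
}

as_mask <- function(x) {
  if (inherits(x, "cell_mask")) return(x)
  if (inherits(x, "baseline_network") || inherits(x, "scenario_result"))
    return(x$mask)
  stop("cannot interpret object of class ", paste(class(x), collapse = "/"),
       " as a cell mask")
}

new_scenario_result <- function(name, mask, land, inclusion_frequency = NULL,
                                objective_report = NULL, extra = list(),
                                provenance = list()) {
  if (is.null(inclusion_frequency))
    inclusion_frequency <- raster_layer(mask$grid, mask$included * 1,
                                        kind = "continuous")
  structure(c(list(scenario = name, mask = mask,
                   inclusion_frequency = inclusion_frequency,
                   achieved_fraction = coverage_fraction(mask, land),
                   objective_report = objective_report,
                   provenance = provenance),
              extra),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("<scenario_result:%s> %d cells, %.2f%% of land\n",
              x$scenario, mask_cells(x$mask), 100 * x$achieved_fraction))
  invisible(x)
}

# number of land cells a coverage target corresponds to
target_cells <- function(config, land) round(config$total_target_fraction * mask_cells(land))

#' Biodiversity-based expansion scenario
#'
#' Locks in the current baseline network plus all key biodiversity areas and
#' expands it to the total coverage target by greedy minimum-shortfall
#' selection over the conservation features (species with range-size targets,
#' ecoregions at their fractional targets). If the greedy selection saturates
#' every attainable target before the budget is spent, the remaining budget is
#' filled with candidate cells in row-major order so the scenario still
#' reaches the coverage target.
#'
#' @param features list of `conservation_feature`s.
#' @param baseline baseline network (or its `cell_mask`).
#' @param kbas `cell_mask` of key biodiversity area cells.
#' @param config a `scenario_config`.
#' @param grid the analysis `c30_grid`.
#' @param land land `cell_mask`.
#' @return a `scenario_result`.
#' @export
build_biodiversity_scenario <- function(features, baseline, kbas, config, grid,
                                        land) {
  base <- as_mask(baseline)
  locked <- mask_union(base, mask_intersect(kbas, land))
  n_target <- target_cells(config, land)
  n_locked <- mask_cells(locked)
  if (n_locked > n_target)
    stop(sprintf("locked-in area (%d cells) already exceeds the %d-cell target by %d cells",
                 n_locked, n_target, n_locked - n_target))
  budget <- n_target - n_locked
  sel <- min_shortfall_select(features, locked, budget, grid, candidates = land)
  mask <- sel$mask
  short <- budget - length(sel$added)
  if (short > 0) {  # early stop: pad in row-major order to reach the target
    cand <- land$included & !mask$included
    rm_idx <- row_major_index(grid)
    pad <- which(cand)[order(rm_idx[cand])][seq_len(min(short, sum(cand)))]
    inc <- mask$included
    inc[pad] <- TRUE
    mask <- cell_mask(grid, inc)
  }
  obj <- shortfall_objective(features, mask)
  new_scenario_result("biodiversity", mask, land,
                      objective_report = obj$report,
                      extra = list(objective = obj$objective,
                                   locked = locked),
                      provenance = list(seed = config$seed, config = config))
}

#' NCP priority-ranking expansion scenario
#'
#' Treats the baseline network as the highest priority, then selects land
#' cells in descending order of the nature's-contributions-to-people priority
#' rank until the coverage target is reached; the final partial step is
#' resolved row-major. Also reports the share of total rank value captured by
#' the selection (computed on the original rank, before the baseline
#' override).
#'
#' @param rank a continuous `raster_layer`, higher = higher priority.
#' @param baseline baseline network (or its `cell_mask`).
#' @param config a `scenario_config`.
#' @param grid the analysis `c30_grid`.
#' @param land land `cell_mask`.
#' @return a `scenario_result` with an extra `captured_value_share` field.
#' @export
build_ncp_scenario <- function(rank, baseline, config, grid, land) {
  check_same_grid(rank$grid, grid, "rank and grid")
  base <- as_mask(baseline)
  rv <- rank$values
  rv[!land$included] <- NA
  if (all(is.na(rv))) stop("priority rank is all nodata on land")
  n_target <- target_cells(config, land)
  pri <- rv
  pri[base$included] <- Inf  # baseline always first
  land_cells <- which(land$included)
  rm_idx <- row_major_index(grid)
  ord <- land_cells[order(-pri[land_cells], rm_idx[land_cells], na.last = TRUE)]
  n_take <- max(n_target, mask_cells(base))  # baseline never removed
  take <- ord[seq_len(min(n_take, length(ord)))]
  inc <- matrix(FALSE, grid$n_rows, grid$n_cols)
  inc[take] <- TRUE
  inc[base$included] <- TRUE
  mask <- cell_mask(grid, inc)
  tot <- sum(rv, na.rm = TRUE)
  captured <- if (tot > 0) sum(rv[mask$included], na.rm = TRUE) / tot else NA_real_
  new_scenario_result("ncp", mask, land,
                      extra = list(captured_value_share = captured),
                      provenance = list(seed = config$seed, config = config))
}

#' Indigenous and traditional territories expansion scenario
#'
#' Builds the territories layer and trims it stochastically to the coverage
#' target: (1) point-format community conserved area (ICCA) records are
#' buffered to their reported area; (2) territory geometries flagged "subject
#' to other special rights" are dropped; (3) the ICCA and territory geometries
#' are rasterized jointly (union coverage), thresholded at 50 percent, and
#' united with the baseline network; (4) candidate cells (neither ICCA nor
#' baseline) with Human Modification Index above the threshold are excluded;
#' (5) if coverage still exceeds the target, eligible cells (again neither
#' ICCA nor baseline) are removed uniformly at random until the target is met,
#' independently in each of `config$replicates` replicates seeded
#' `seed + 1 ... seed + R`. The reference mask is replicate 1;
#' `inclusion_frequency` is the per-cell mean over replicates.
#'
#' @param iplc_lands list of entries `list(geometry = c30_geom, rights_flag =
#'   "none" | "subject_to_other_special_rights")`.
#' @param icca_records list of `pa_record`s (points allowed).
#' @param baseline baseline network (or its `cell_mask`).
#' @param hmi Human Modification Index `raster_layer` in `[0, 1]`.
#' @param config a `scenario_config`.
#' @param grid the analysis `c30_grid`.
#' @param land land `cell_mask`.
#' @param keep_replicates keep the per-replicate masks (needed for
#'   replicate-averaged statistics; default TRUE).
#' @return a `scenario_result` with extra fields `replicate_masks` (list of
#'   logical matrices) and `fixed` (the never-removed `cell_mask`).
#' @export
build_itt_scenario <- function(iplc_lands, icca_records, baseline, hmi, config,
                               grid, land, keep_replicates = TRUE) {
  check_same_grid(hmi$grid, grid, "hmi and grid")
  base <- as_mask(baseline)

  icca <- filter_records(icca_records)
  keep_flags <- vapply(iplc_lands, function(e)
    !identical(e$rights_flag, "subject_to_other_special_rights"), TRUE)
  iplc_geoms <- lapply(iplc_lands[keep_flags], function(e) e$geometry)

  # ICCA cells are identified from the ICCA geometries alone (they are exempt
  # from removal); the scenario body is the joint union coverage.
  icca_cov <- rasterize_coverage(icca$geoms, grid)
  icca_cov$values[!land$included] <- 0
  icca_mask <- threshold_mask(icca_cov)
  cov <- rasterize_coverage(c(icca$geoms, iplc_geoms), grid)
  cov$values[!land$included] <- 0
  body <- mask_union(threshold_mask(cov), base)

  fixed <- mask_union(icca_mask, base)   # never removed, never HMI-filtered
  hmi_ok <- !is.na(hmi$values) & hmi$values <= config$hmi_threshold
  inc <- body$included & (fixed$included | hmi_ok)
  body <- cell_mask(grid, inc)

  n_target <- target_cells(config, land)
  n_fixed_in <- mask_cells(mask_intersect(fixed, body))
  if (n_fixed_in > n_target)
    stop(sprintf("non-removable area (%d cells) alone exceeds the %d-cell target",
                 n_fixed_in, n_target))
  eligible <- which(body$included & !fixed$included)
  n_remove <- max(0, mask_cells(body) - n_target)
  if (n_remove > length(eligible))
    stop("cannot reach the target: not enough removable cells")

  R <- config$replicates
  rep_seeds <- config$seed + seq_len(R)
  freq <- matrix(0, grid$n_rows, grid$n_cols)
  rep_masks <- if (keep_replicates) vector("list", R) else NULL
  first <- NULL
  for (r in seq_len(R)) {
    inc_r <- body$included
    if (n_remove > 0) {
      set.seed(rep_seeds[r])
      inc_r[sample(eligible, n_remove)] <- FALSE
    }
    freq <- freq + inc_r
    if (r == 1) first <- inc_r
    if (keep_replicates) rep_masks[[r]] <- inc_r
  }
  freq <- freq / R
  new_scenario_result("itt", cell_mask(grid, first), land,
                      inclusion_frequency = raster_layer(grid, freq, "continuous"),
                      extra = list(replicate_masks = rep_masks, fixed = fixed),
                      provenance = list(seed = config$seed, config = config,
                                        replicate_seeds = rep_seeds))
}
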