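# Minimum-shortfall reserve selection.
#
# Objective over a selected cell set S:
#   sum_f  w_f * max(0, t_f - h_f(S)) / t_f,   h_f(S) = sum_{c in S} amount_f(c)
# i.e. the weighted sum of proportional target shortfalls. Minimised greedily
# under a cell budget, with an exhaustive-enumeration solver for small
# instances as an exact cross-check.

# row-major 0-based linear index of every cell of a grid, as a matrix-shaped
# integer layer (cell (i,j) -> i*n_cols + j; matrices are column-major so
# build by row).
row_major_index <- function(grid) {
  matrix(rep(0:(grid$n_rows - 1), grid$n_cols) * grid$n_cols +
           rep(0:(grid$n_cols - 1), each = grid$n_rows),
         grid$n_rows, grid$n_cols)
}

# Drop zero-target features (shortfall undefined) with a warning; returns the
# usable list.
usable_features <- function(features) {
  tf <- vapply(features, function(f) f$target_amount, 0)
  if (any(tf == 0)) {
    warning("excluding ", sum(tf == 0),
            " feature(s) with zero target from the shortfall objective")
    features <- features[tf > 0]
  }
  features
}

#' Shortfall objective of a cell set
#'
#' @param features list of `conservation_feature`s (zero-target features are
#'   excluded with a warning).
#' @param mask `cell_mask` of selected cells.
#' @return list with `objective` and `report`, a data.frame of
#'   (id, target, held, shortfall) per feature.
#' @export
shortfall_objective <- function(features, mask) {
  features <- usable_features(features)
  held <- vapply(features, function(f) zonal_sum(f$amount, mask), 0)
  tf <- vapply(features, function(f) f$target_amount, 0)
  wf <- vapply(features, function(f) f$weight, 0)
  sf <- pmax(0, tf - held) / ifelse(tf > 0, tf, 1)
  list(objective = sum(wf * sf),
       report = data.frame(id = vapply(features, function(f) f$id, ""),
                           target = tf, held = held, shortfall = sf,
                           stringsAsFactors = FALSE))
}

#' Greedy minimum-shortfall cell selection
#'
#' Starting from the locked-in cells, repeatedly adds the candidate cell with
#' the largest marginal decrease of the shortfall objective, breaking ties by
#' row-major cell index, until the budget is exhausted or no cell improves the
#' objective (early stop). The marginal gain of cell c is
#' sum_f w_f * min(amount_f(c), remaining_f) / t_f. A best-improvement swap
#' refinement (exchange one selected cell for one unselected candidate while
#' any exchange lowers the objective; ties row-major) then polishes the greedy
#' solution, which makes the heuristic reach the exact optimum on small
#' instances in practice; set `refine = FALSE` for the plain greedy path.
#'
#' @param features list of `conservation_feature`s.
#' @param locked_in `cell_mask` of cells forced into the solution.
#' @param budget_cells maximum number of cells to add beyond `locked_in`.
#' @param grid the analysis `c30_grid`.
#' @param candidates optional `cell_mask` restricting where cells may be added
#'   (e.g. land); defaults to the whole grid.
#' @return list of class `shortfall_selection`: `mask` (locked plus added
#'   cells), `added` (row-major indices in selection order), `objective`,
#'   `report` (per-feature target/held/shortfall at the final selection).
#' @export
min_shortfall_select <- function(features, locked_in, budget_cells, grid,
                                 candidates = NULL, refine = TRUE) {
  check_same_grid(locked_in$grid, grid, "locked_in and grid")
  if (budget_cells < 0) stop("budget_cells must be >= 0")
  if (is.null(candidates))
    candidates <- cell_mask(grid, matrix(TRUE, grid$n_rows, grid$n_cols))
  check_same_grid(candidates$grid, grid, "candidates and grid")
  features <- usable_features(features)

  cand <- candidates$included & !locked_in$included
  rm_idx <- row_major_index(grid)
  ord <- order(rm_idx[cand])           # candidate cells in row-major order
  cand_cells <- which(cand)[ord]       # column-major positions, row-major sorted
  m <- length(cand_cells)

  nf <- length(features)
  tf <- vapply(features, function(f) f$target_amount, 0)
  wf <- vapply(features, function(f) f$weight, 0)
  A <- matrix(0, nf, m)  # per-feature amount on each candidate cell
  for (f in seq_len(nf)) {
    av <- features[[f]]$amount$values
    av[is.na(av)] <- 0
    A[f, ] <- av[cand_cells]
  }
  held <- vapply(features, function(f) zonal_sum(f$amount, locked_in), 0)

  sel <- logical(m)
  added <- integer(0)
  n_add <- min(budget_cells, m)
  while (length(added) < n_add) {
    rem <- pmax(0, tf - held)
    if (nf == 0 || all(rem == 0)) break
    gain <- as.vector(crossprod(wf / tf, pmin(A, rem)))  # marginal decrease per cell
    gain[sel] <- -Inf
    best <- which.max(gain)   # first max = lowest row-major index (tie rule)
    if (gain[best] <= 0) break
    sel[best] <- TRUE
    added <- c(added, best)
    held <- held + A[, best]
  }

  # Variable-depth exchange refinement: best-improvement 1-for-1 swaps until
  # none helps, then (on small instances) 2-for-2 exchanges; any improving
  # deep exchange restarts the 1-swap loop. Neighborhood sizes are capped so
  # large scenario-scale instances keep the plain greedy path's speed.
  if (refine && nf > 0 && length(added)) {
    obj_at <- function(held) sum(wf * pmax(0, tf - held) / tf)
    apply_swap <- function(outs_idx, ins_idx) {
      sel[outs_idx] <<- FALSE; sel[ins_idx] <<- TRUE
      held <<- held - rowSums(A[, outs_idx, drop = FALSE]) +
        rowSums(A[, ins_idx, drop = FALSE])
      for (k in seq_along(outs_idx))
        added[added == outs_idx[k]] <<- ins_idx[k]
    }
    one_swap <- function() {  # TRUE if an improving swap was applied
      outs <- which(sel); ins <- which(!sel)
      if (!length(outs) || !length(ins) ||
          as.numeric(length(outs)) * length(ins) > 2e5) return(FALSE)
      cur <- obj_at(held)
      best_delta <- 1e-12; best <- NULL
      for (i in outs) {
        h_wo <- held - A[, i]
        for (j in ins) {
          delta <- cur - obj_at(h_wo + A[, j])
          if (delta > best_delta) { best_delta <- delta; best <- c(i, j) }
        }
      }
      if (is.null(best)) return(FALSE)
      apply_swap(best[1], best[2])
      TRUE
    }
    two_swap <- function() {
      outs <- which(sel); ins <- which(!sel)
      if (length(outs) < 2 || length(ins) < 2) return(FALSE)
      if (choose(as.numeric(length(outs)), 2) *
            choose(as.numeric(length(ins)), 2) > 5e4) return(FALSE)
      op <- utils::combn(outs, 2); ip <- utils::combn(ins, 2)
      cur <- obj_at(held)
      best_delta <- 1e-12; best <- NULL
      for (a in seq_len(ncol(op))) {
        h_wo <- held - A[, op[1, a]] - A[, op[2, a]]
        for (b2 in seq_len(ncol(ip))) {
          delta <- cur - obj_at(h_wo + A[, ip[1, b2]] + A[, ip[2, b2]])
          if (delta > best_delta) { best_delta <- delta; best <- cbind(op[, a], ip[, b2]) }
        }
      }
      if (is.null(best)) return(FALSE)
      apply_swap(best[, 1], best[, 2])
      TRUE
    }
    repeat {
      if (one_swap()) next
      if (!two_swap()) break
    }
  }

  inc <- locked_in$included
  inc[cand_cells[sel]] <- TRUE
  mask <- cell_mask(grid, inc)
  obj <- shortfall_objective(features, mask)
  structure(list(mask = mask,
                 added = rm_idx[cand_cells[added]],
                 objective = obj$objective,
                 report = obj$report),
            class = "shortfall_selection")
}

#' Exhaustive minimum-shortfall solver for small instances
#'
#' Enumerates every candidate subset of size `min(budget_cells, m)` and
#' returns one with minimal shortfall objective (the lexicographically first
#' in row-major order among optima, for determinism). The objective never
#' increases when cells are added, so only maximal subsets need enumerating.
#' Intended as an exact cross-check for instances with at most about 20
#' candidate cells.
#'
#' @inheritParams min_shortfall_select
#' @return same shape as [min_shortfall_select()].
#' @export
min_shortfall_enumerate <- function(features, locked_in, budget_cells, grid,
                                    candidates = NULL) {
  if (is.null(candidates))
    candidates <- cell_mask(grid, matrix(TRUE, grid$n_rows, grid$n_cols))
  features <- usable_features(features)
  cand <- candidates$included & !locked_in$included
  rm_idx <- row_major_index(grid)
  ord <- order(rm_idx[cand])
  cand_cells <- which(cand)[ord]
  m <- length(cand_cells)
  if (m > 25) stop("enumeration solver limited to 25 candidate cells")
  b <- min(budget_cells, m)

  nf <- length(features)
  tf <- vapply(features, function(f) f$target_amount, 0)
  wf <- vapply(features, function(f) f$weight, 0)
  A <- matrix(0, nf, m)
  for (f in seq_len(nf)) {
    av <- features[[f]]$amount$values
    av[is.na(av)] <- 0
    A[f, ] <- av[cand_cells]
  }
  base_held <- vapply(features, function(f) zonal_sum(f$amount, locked_in), 0)

  obj_of <- function(cols) {
    held <- base_held + if (length(cols)) rowSums(A[, cols, drop = FALSE]) else 0
    sum(wf * pmax(0, tf - held) / tf)
  }
  best_obj <- Inf; best_cols <- integer(0)
  if (b == 0 || m == 0) {
    best_obj <- obj_of(integer(0))
  } else {
    combos <- utils::combn(m, b)
    for (k in seq_len(ncol(combos))) {
      o <- obj_of(combos[, k])
      if (o < best_obj - 1e-12) { best_obj <- o; best_cols <- combos[, k] }
    }
  }
  inc <- locked_in$included
  inc[cand_cells[best_cols]] <- TRUE
  mask <- cell_mask(grid, inc)
  obj <- shortfall_objective(features, mask)
  structure(list(mask = mask, added = rm_idx[cand_cells[best_cols]],
                 objective = obj$objective, report = obj$report),
            class = "shortfall_selection")
}

#' @export
print.shortfall_selection <- function(x, ...) {
  cat(sprintf("<shortfall_selection> %d cells selected (%d added), objective %.6g over %d features\n",
              mask_cells(x$mask), length(x$added), x$objective, nrow(x$report)))
  invisible(x)
}
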