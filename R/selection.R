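#' Choose the desirability-index threshold from the separation constraint
#'
#' The screening threshold is the smallest desirability-index value `t`
#' (searched over the sorted distinct observed index values — admissibility
#' can only change there) such that every condition with index >= `t` has a
#' strictly positive separation criterion: conditions deemed acceptable must
#' never imply predicted co-elution at baseline.
#'
#' @param index Desirability-index surface (matrix).
#' @param separation Separation surface (matrix, same shape, minutes).
#' @return The threshold value.
#' @export
auto_threshold <- function(index, separation) {
  if (!identical(dim(index), dim(separation)))
    stop("'index' and 'separation' must share a grid", call. = FALSE)
  if (!any(separation > 0))
    stop("no condition on the grid separates the sample (separation <= 0 ",
         "everywhere); screening cannot select conditions", call. = FALSE)
  for (t in sort(unique(as.vector(index)))) {
    if (all(separation[index >= t] > 0)) return(t)
  }
  # unreachable while some separation > 0 exists at the top index, but be
  # explicit: the argmax cell itself co-elutes
  stop("every condition at the maximal desirability index has ",
       "separation <= 0; screening cannot select conditions", call. = FALSE)
}

#' Segment the grid into robust candidate regions
#'
#' Thresholds the weight-robustness probability surface at
#' `probability_threshold` (default 0.30 — a modest chance of reaching the
#' desirability target suffices at the screening stage) and labels the
#' connected components of the admissible cell set, under 8-connectivity by
#' default (diagonal neighbours joined). Regions are sorted by size
#' descending; ties broken by lower minimum pH index, then lower minimum tG
#' index, so results do not depend on traversal order.
#'
#' @param probability Probability surface (matrix, pH x tG) from
#'   [probability_surface()].
#' @param probability_threshold Value in (0, 1); cells with
#'   `P >= probability_threshold` are admissible.
#' @param connectivity 8 (default) or 4.
#' @return List of regions, each a list with `cells` (data frame with
#'   `ph_idx`, `tg_idx`), `size`. Empty list when no cell is admissible (a
#'   valid screening outcome).
#' @export
segment_regions <- function(probability, probability_threshold = 0.30,
                            connectivity = 8) {
  if (!is.matrix(probability))
    stop("'probability' must be a matrix", call. = FALSE)
  if (probability_threshold <= 0 || probability_threshold >= 1)
    stop("'probability_threshold' must be in (0, 1)", call. = FALSE)
  if (!connectivity %in% c(4, 8))
    stop("'connectivity' must be 4 or 8", call. = FALSE)
  mask <- probability >= probability_threshold
  labels <- label_components(mask, connectivity)
  ids <- setdiff(unique(as.vector(labels)), 0L)
  regions <- lapply(ids, function(id) {
    idx <- which(labels == id, arr.ind = TRUE)
    cells <- data.frame(ph_idx = idx[, 1], tg_idx = idx[, 2])
    cells <- cells[order(cells$ph_idx, cells$tg_idx), , drop = FALSE]
    rownames(cells) <- NULL
    list(cells = cells, size = nrow(cells))
  })
  ord <- order(-vapply(regions, `[[`, integer(1), "size"),
               vapply(regions, function(r) min(r$cells$ph_idx), integer(1)),
               vapply(regions, function(r) min(r$cells$tg_idx), integer(1)))
  regions[ord]
}

# connected-component labels of a logical matrix: admissible cells become a
# graph with edges between (diagonally) adjacent admissible cells, labeled
# by igraph's component finder; 0 = background
label_components <- function(mask, connectivity = 8) {
  labels <- matrix(0L, nrow(mask), ncol(mask))
  cells <- which(mask)
  if (!length(cells)) return(labels)
  nr <- nrow(mask)
  offsets <- if (connectivity == 4) {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  } else {
    cbind(rep(-1:1, 3), rep(-1:1, each = 3))[-5, ]
  }
  pos <- arrayInd(cells, dim(mask))
  cell_id <- integer(length(mask)); cell_id[cells] <- seq_along(cells)
  edges <- NULL
  for (k in seq_len(nrow(offsets))) {
    nbr_r <- pos[, 1] + offsets[k, 1]
    nbr_c <- pos[, 2] + offsets[k, 2]
    ok <- nbr_r >= 1 & nbr_r <= nr & nbr_c >= 1 & nbr_c <= ncol(mask)
    nbr_lin <- (nbr_c[ok] - 1L) * nr + nbr_r[ok]
    ok2 <- mask[nbr_lin]
    edges <- rbind(edges,
                   cbind(cell_id[cells[ok]][ok2], cell_id[nbr_lin][ok2]))
  }
  if (is.null(edges) || !nrow(edges)) {
    labels[cells] <- seq_along(cells)   # all isolated
    return(labels)
  }
  edges <- unique(cbind(pmin(edges[, 1], edges[, 2]),
                        pmax(edges[, 1], edges[, 2])))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(cells) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  labels[cells] <- as.integer(comp[seq_along(cells)])
  labels
}

#' Global and largest-region optimal conditions
#'
#' The two conditions worth carrying into the optimization phase: the grid
#' condition with the highest desirability index overall (global optimum),
#' and the highest-index condition inside the largest robust region
#' (largest-region optimum) — the latter gives room to move the condition
#' later in the method's lifecycle without redeveloping it. Ties are broken
#' by lower pH, then lower gradient time.
#'
#' @param index Desirability-index surface (matrix, pH x tG).
#' @param regions Region list from [segment_regions()].
#' @param grid The [condition_grid()].
#' @return List with `global_optimum` and `largest_region_optimum` (the
#'   latter `NULL` when there are no regions), each a list with `ph`, `tg`,
#'   `ph_idx`, `tg_idx`, `value`; plus `region_table`, a data frame
#'   summarizing every region (size, best condition, best value).
#' @export
select_optima <- function(index, regions, grid) {
  stopifnot(inherits(grid, "condition_grid"))
  all_cells <- expand.grid(ph_idx = seq_along(grid$ph_values),
                           tg_idx = seq_along(grid$tg_values))
  global_opt <- argmax_cells(index, all_cells, grid)
  region_best <- lapply(regions, function(r) argmax_cells(index, r$cells, grid))
  region_table <- if (length(regions)) {
    data.frame(
      region_id = seq_along(regions),
      size = vapply(regions, `[[`, integer(1), "size"),
      best_ph = vapply(region_best, `[[`, numeric(1), "ph"),
      best_tg = vapply(region_best, `[[`, numeric(1), "tg"),
      best_index = vapply(region_best, `[[`, numeric(1), "value"))
  } else {
    data.frame(region_id = integer(0), size = integer(0),
               best_ph = numeric(0), best_tg = numeric(0),
               best_index = numeric(0))
  }
  list(global_optimum = global_opt,
       largest_region_optimum = if (length(regions)) region_best[[1]] else NULL,
       region_table = region_table)
}

# argmax of a surface restricted to a cell set, ties broken by lower pH
# then lower tG
argmax_cells <- function(index, cells, grid) {
  vals <- index[cbind(cells$ph_idx, cells$tg_idx)]
  best <- which(vals == max(vals))
  best <- best[order(cells$ph_idx[best], cells$tg_idx[best])][1]
  list(ph = grid$ph_values[cells$ph_idx[best]],
       tg = grid$tg_values[cells$tg_idx[best]],
       ph_idx = cells$ph_idx[best], tg_idx = cells$tg_idx[best],
       value = vals[best])
}
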