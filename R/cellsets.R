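# Partitioning of wing cells into up to five user-defined sets for
# localized asymmetry comparison.

#' Assign wing cells to sets
#'
#' Cells may be assigned by explicit cell-id lists or by polygonal regions
#' (cells whose centroid lies inside a polygon belong to that set). A wing
#' carries at most five sets, each with at least three cells; sets are
#' disjoint, and cells falling in no set are simply excluded from the
#' per-set analysis.
#'
#' @param wing A `wa_geometry` object.
#' @param sets For `mode = "ids"`, a list of integer cell-id vectors; for
#'   `mode = "polygons"`, a list of n x 2 (row, col) vertex matrices.
#' @param mode `"ids"` or `"polygons"`.
#' @param labels Optional set names (default `"Set 1"` ...).
#' @return A `wa_cellsets` object: list with `sets` (list of cell-id
#'   vectors), `labels`, `mode`.
#' @export
assign_sets <- function(wing, sets, mode = c("ids", "polygons"),
                        labels = NULL) {
  stopifnot(inherits(wing, "wa_geometry"), is.list(sets))
  mode <- match.arg(mode)
  if (length(sets) < 1) stop("at least one set required")
  if (length(sets) > 5) stop("too many sets: at most 5 allowed")
  if (is.null(labels)) labels <- paste("Set", seq_along(sets))

  ids <- if (mode == "ids") {
    lapply(sets, function(s) {
      s <- as.integer(s)
      if (!all(s %in% wing$cells$cell_id))
        stop("unknown cell id in set definition")
      s
    })
  } else {
    cent <- cbind(wing$cells$centroid_row, wing$cells$centroid_col)
    lapply(sets, function(poly) {
      poly <- as.matrix(poly)
      if (ncol(poly) != 2 || nrow(poly) < 3)
        stop("polygon must be an n x 2 matrix with >= 3 vertices")
      wing$cells$cell_id[mgcv::in.out(poly, cent)]
    })
  }
  sizes <- vapply(ids, length, 1L)
  if (any(sizes < 3))
    stop("set below minimum size: every set needs at least 3 cells")
  if (anyDuplicated(unlist(ids)))
    stop("duplicate assignment: sets must be disjoint")
  structure(list(sets = ids, labels = labels, mode = mode),
            class = "wa_cellsets")
}

#' Read a cell-set specification from JSON
#'
#' Format: `{"mode": "ids", "sets": [[1,2,3], ...]}` or
#' `{"mode": "polygons", "sets": [[[r,c], [r,c], ...], ...]}`.
#'
#' @param path Path to the JSON file.
#' @return List with `mode` and `sets` ready for [assign_sets()].
#' @export
read_cellsets <- function(path) {
  spec <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  if (!spec$mode %in% c("ids", "polygons"))
    stop("cell-set mode must be 'ids' or 'polygons'")
  sets <- if (is.matrix(spec$sets)) {
    lapply(seq_len(nrow(spec$sets)), function(i) spec$sets[i, ])
  } else as.list(spec$sets)
  list(mode = spec$mode, sets = sets)
}

#' Per-set asymmetry metrics
#'
#' For each set index, cell matching is restricted to the cells of that
#' set on each wing (sets correspond across wings by index), and the full
#' per-direction regression/NRMSE battery plus set total areas and
#' centroid distance statistics are computed.
#'
#' @param wing1,wing2 Segmented `wa_geometry` objects.
#' @param partition1,partition2 `wa_cellsets` for each wing (same number
#'   of sets).
#' @param transform `wa_transform` superimposing wing 2 onto wing 1.
#' @return Data frame with one row per set x direction x metric:
#'   `set_label, direction, metric, slope, intercept, r2, nrmse,
#'   set_area_1, set_area_2, centroid_dist_mean, centroid_dist_sd`.
#' @export
evaluate_sets <- function(wing1, wing2, partition1, partition2,
                          transform = rigid_transform()) {
  stopifnot(inherits(partition1, "wa_cellsets"),
            inherits(partition2, "wa_cellsets"))
  if (length(partition1$sets) != length(partition2$sets))
    stop("set-count mismatch between wings")
  w2 <- apply_transform(wing2, transform)
  s <- wing1$scale %||% 1

  rows <- lapply(seq_along(partition1$sets), function(k) {
    g1 <- subset_cells(wing1, partition1$sets[[k]])
    g2 <- subset_cells(w2, partition2$sets[[k]])
    cor1 <- match_cells(g1, g2)
    cor2 <- match_cells(g2, g1)
    m <- rbind(direction_metrics(g1$cells, g2$cells, cor1, 1L),
               direction_metrics(g2$cells, g1$cells, cor2, 2L))
    dist_by_dir <- list(cor1$distance * s, cor2$distance * s)
    m$set_label <- partition1$labels[k]
    m$set_area_1 <- sum(g1$cells$area)
    m$set_area_2 <- sum(g2$cells$area)
    m$centroid_dist_mean <- vapply(m$direction,
                                   function(d) mean(dist_by_dir[[d]]), 1)
    m$centroid_dist_sd <- vapply(m$direction,
                                 function(d) pop_sd(dist_by_dir[[d]]), 1)
    m
  })
  out <- do.call(rbind, rows)
  out[, c("set_label", "direction", "metric", "slope", "intercept", "r2",
          "nrmse", "set_area_1", "set_area_2", "centroid_dist_mean",
          "centroid_dist_sd")]
}

# Restrict a geometry to the given cell ids (keeps outline/junctions).
subset_cells <- function(wing, ids) {
  wing$cells <- wing$cells[wing$cells$cell_id %in% ids, , drop = FALSE]
  wing$n_cells <- nrow(wing$cells)
  wing
}
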