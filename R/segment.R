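# Region-growing segmentation of membrane cells and the wing outline.
#
# Conventions: coordinates are (row, col), 1-based, origin top-left, row
# increasing downward. Membrane (light) pixels form the foreground with
# 8-connectivity; veins (dark) are the complementary phase. The light
# component(s) touching the image border are the background, everything
# else inside the outline is wing.

#' Grow a single cell region from a seed pixel
#'
#' Flood-fills the 8-connected foreground (membrane) component containing
#' the seed. Every vein pixel 8-adjacent to a claimed pixel is recorded as
#' the cell boundary, in encounter order. Cell metrics follow
#' [cell_metrics()].
#'
#' @param image A `wa_binary` object.
#' @param seed Integer `(row, col)` of a foreground pixel.
#' @return A `wa_cell` object: list with `interior` and `boundary`
#'   coordinate matrices and the metric fields `area`, `length`, `width`,
#'   `circularity`, `perimeter`, `centroid`.
#' @export
grow_region <- function(image, seed) {
  stopifnot(inherits(image, "wa_binary"))
  seed <- as.integer(seed)
  if (length(seed) != 2) stop("seed must be a (row, col) pair")
  res <- region_grow_cpp(image$mask, seed[1], seed[2])
  region <- list(interior = res$interior, boundary = res$boundary)
  m <- cell_metrics(region, scale = image$scale %||% 1)
  structure(c(region, m), class = "wa_cell")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Compute cell morphometrics
#'
#' Area is the interior pixel count (times scale squared); length is the
#' maximum pairwise Euclidean distance between boundary pixels (at least
#' 1 px to keep degenerate regions finite); width is area / length;
#' circularity is the dimensionless `4 * pi * area / perimeter^2`, computed
#' in pixel units so it is scale-invariant. The perimeter is the traced
#' 8-connected contour length of the interior region (axial steps 1,
#' diagonal steps sqrt(2)).
#'
#' @param region List with `interior` (n x 2) and `boundary` (m x 2)
#'   coordinate matrices.
#' @param scale Length units per pixel (default 1 = pixel units).
#' @return List with `area`, `length`, `width`, `circularity`, `perimeter`,
#'   `centroid` (row, col).
#' @export
cell_metrics <- function(region, scale = 1) {
  interior <- region$interior
  if (is.null(interior) || nrow(interior) == 0) stop("empty region")
  area_px <- nrow(interior)
  boundary <- region$boundary
  len_px <- if (!is.null(boundary) && nrow(boundary) > 0)
    max_pairwise_dist(boundary) else 0
  len_px <- max(1, len_px)
  # trace the interior contour for the perimeter
  rmin <- min(interior[, 1]); cmin <- min(interior[, 2])
  sub <- matrix(0L, max(interior[, 1]) - rmin + 1, max(interior[, 2]) - cmin + 1)
  sub[cbind(interior[, 1] - rmin + 1, interior[, 2] - cmin + 1)] <- 1L
  per_px <- trace_contour_cpp(sub, 1L)$length
  per_px <- max(per_px, 1)
  list(area = area_px * scale^2,
       length = len_px * scale,
       width = area_px * scale^2 / (len_px * scale),
       circularity = 4 * pi * area_px / per_px^2,
       perimeter = per_px * scale,
       centroid = c(row = mean(interior[, 1]), col = mean(interior[, 2])))
}

#' Extract the wing outline
#'
#' The wing silhouette is the complement of the border-touching light
#' background component (cells and veins filled solid). Its external
#' boundary is traced as an ordered closed polyline; interior holes are
#' ignored. If several disjoint silhouettes exist, the largest is kept with
#' a warning.
#'
#' @param image A `wa_binary` object.
#' @return List with `outline` (n x 2 ordered closed polyline of (row, col)
#'   points), `wing_area`, `wing_length`, `wing_width`, `wing_perimeter`
#'   (in scaled units), and `silhouette` (logical matrix).
#' @export
extract_outline <- function(image) {
  stopifnot(inherits(image, "wa_binary"))
  mask <- image$mask
  labels <- cc_label_cpp(mask, 8L)
  bg <- setdiff(unique(c(labels[1, ], labels[nrow(labels), ],
                         labels[, 1], labels[, ncol(labels)])), 0L)
  sil <- matrix(TRUE, nrow(mask), ncol(mask))
  if (length(bg)) sil[labels %in% bg] <- FALSE
  if (!any(sil)) stop("no wing silhouette: image is all background")
  comp <- cc_label_cpp(sil, 8L)
  sizes <- tabulate(comp[comp > 0])
  if (length(sizes) > 1)
    warning("multiple disjoint silhouettes; keeping the largest")
  keep <- which.max(sizes)
  sil <- comp == keep
  tr <- trace_contour_cpp(comp, keep)
  s <- image$scale %||% 1
  outline <- tr$path
  wing_area <- sum(sil) * s^2
  wing_length <- max(1, max_pairwise_dist(outline)) * s
  list(outline = outline,
       wing_area = wing_area,
       wing_length = wing_length,
       wing_width = wing_area / wing_length,
       wing_perimeter = max(tr$length, 1) * s,
       silhouette = sil)
}

#' Segment a binarized wing into cells, outline and junctions
#'
#' Scans pixels in row-major order and grows a region at each unclaimed
#' foreground pixel. Light components touching the image border are
#' classified as background; the remaining components, filtered by a
#' minimum area, become cells with ids assigned in discovery order. The
#' outline and whole-wing metrics come from [extract_outline()], and vein
#' junctions (optionally) from [skeletonize()] + [detect_junctions()].
#'
#' @param image A `wa_binary` object.
#' @param min_cell_area Minimum cell area in pixels (default 8); smaller
#'   speckle components are discarded.
#' @param junctions If `TRUE` (default), skeletonize the vein network and
#'   detect junctions.
#' @param prune_spurs Minimum skeleton branch length in px below which open
#'   spurs are pruned before junction detection (default 5).
#' @return A `wa_geometry` object: list with `cells` (data frame
#'   `cell_id, centroid_row, centroid_col, area, length, width,
#'   circularity, perimeter`), `cell_boundaries` (list of coordinate
#'   matrices), `outline`, `junctions` (data frame), whole-wing metrics,
#'   counts, `scale` and `dims`.
#' @export
segment_all <- function(image, min_cell_area = 8, junctions = TRUE,
                        prune_spurs = 5) {
  stopifnot(inherits(image, "wa_binary"))
  mask <- image$mask
  if (!any(mask)) stop("empty image: no foreground pixels")
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- cc_label_cpp(mask, 8L)
  bg <- setdiff(unique(c(labels[1, ], labels[nr, ], labels[, 1], labels[, nc])), 0L)

  out <- tryCatch(extract_outline(image), error = function(e) {
    # image entirely background (e.g. all light): no wing, zero cells
    warning(conditionMessage(e))
    list(outline = matrix(numeric(0), 0, 2), wing_area = 0, wing_length = 0,
         wing_width = 0, wing_perimeter = 0,
         silhouette = matrix(FALSE, nr, nc))
  })
  sil <- out$silhouette
  if (any(sil[1, ]) && any(sil[nr, ]) && any(sil[, 1]) && any(sil[, nc]))
    warning("wing silhouette touches all four image borders; ",
            "background/wing separation may be ambiguous")

  sizes <- tabulate(labels[labels > 0])
  cand <- setdiff(seq_along(sizes), bg)
  cand <- cand[sizes[cand] >= min_cell_area]
  s <- image$scale %||% 1

  # per-cell boundary pixels: vein pixels 8-adjacent to each cell
  cell_lab <- matrix(0L, nr, nc)
  if (length(cand)) {
    remap <- integer(length(sizes)); remap[cand] <- seq_along(cand)
    fg <- labels > 0
    cell_lab[fg] <- remap[labels[fg]]
  }
  dark <- !mask
  dark_idx <- which(dark)
  bnd <- vector("list", length(cand))
  if (length(cand) && length(dark_idx)) {
    offs <- rbind(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
                  c(1, 0), c(1, -1), c(0, -1), c(-1, -1))
    acc_i <- integer(0); acc_l <- integer(0)
    for (k in seq_len(8)) {
      sh <- shift_mat(cell_lab, offs[k, 1], offs[k, 2], 0L)
      hit <- dark_idx[sh[dark_idx] > 0]
      acc_i <- c(acc_i, hit); acc_l <- c(acc_l, sh[hit])
    }
    if (length(acc_i)) {
      dup <- duplicated(cbind(acc_i, acc_l))
      acc_i <- acc_i[!dup]; acc_l <- acc_l[!dup]
      rr <- ((acc_i - 1) %% nr) + 1; cc <- ((acc_i - 1) %/% nr) + 1
      sp <- split(seq_along(acc_i), acc_l)
      for (nm in names(sp))
        bnd[[as.integer(nm)]] <- cbind(row = rr[sp[[nm]]], col = cc[sp[[nm]]])
    }
  }

  cells <- data.frame(cell_id = integer(0), centroid_row = numeric(0),
                      centroid_col = numeric(0), area = numeric(0),
                      length = numeric(0), width = numeric(0),
                      circularity = numeric(0), perimeter = numeric(0))
  if (length(cand)) {
    idx <- which(cell_lab > 0)
    lab_v <- cell_lab[idx]
    rr <- ((idx - 1) %% nr) + 1; cc <- ((idx - 1) %/% nr) + 1
    area_px <- tabulate(lab_v, nbins = length(cand))
    cr <- rowsum(rr, lab_v)[, 1] / area_px
    ccol <- rowsum(cc, lab_v)[, 1] / area_px
    len_px <- per_px <- numeric(length(cand))
    for (i in seq_along(cand)) {
      b <- bnd[[i]]
      len_px[i] <- max(1, if (!is.null(b)) max_pairwise_dist(b) else 0)
      per_px[i] <- max(1, trace_contour_cpp(cell_lab, i)$length)
    }
    cells <- data.frame(cell_id = seq_along(cand),
                        centroid_row = cr, centroid_col = ccol,
                        area = area_px * s^2,
                        length = len_px * s,
                        width = (area_px * s^2) / (len_px * s),
                        circularity = 4 * pi * area_px / per_px^2,
                        perimeter = per_px * s)
    rownames(cells) <- NULL
  }

  jn <- data.frame(junction_id = integer(0), row = numeric(0), col = numeric(0))
  if (junctions) {
    sk <- skeletonize(image)
    jn <- detect_junctions(sk, prune = prune_spurs)
  }

  structure(list(cells = cells, cell_boundaries = bnd,
                 outline = out$outline, junctions = jn,
                 wing_area = out$wing_area, wing_length = out$wing_length,
                 wing_width = out$wing_width,
                 wing_perimeter = out$wing_perimeter,
                 n_cells = nrow(cells), n_junctions = nrow(jn),
                 scale = s, dims = c(nr, nc)),
            class = "wa_geometry")
}

#' @export
print.wa_geometry <- function(x, ...) {
  cat("<wa_geometry> ", x$n_cells, " cells, ", x$n_junctions, " junctions; ",
      "wing area ", signif(x$wing_area, 6),
      ", length ", signif(x$wing_length, 6),
      ", perimeter ", signif(x$wing_perimeter, 6),
      if (x$scale != 1) paste0(" (scale ", x$scale, ")"), "\n", sep = "")
  invisible(x)
}
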