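# Deterministic synthetic wing-pair generator with exact ground truth.
#
# The venation is a centroidally relaxed Voronoi tessellation of an
# ellipse-like blade silhouette, rasterized as dark strokes of configurable
# width on a light background. Voronoi geometry gives exact polygonal
# ground truth for cell areas, centroids and vertices, which is what the
# measurement contracts need; biological realism of the vein tree is not
# the goal.

#' Synthetic wing configuration
#'
#' @param seed Integer RNG seed; with a fixed seed the generator output is
#'   bit-identical across runs.
#' @param n_cells Target number of cells (>= 10).
#' @param height,width Image size in pixels.
#' @param vein_width Vein stroke width in px (>= 2).
#' @param area_scale Left/right cell-area ratio, applied as a global
#'   geometric scaling of the left wing by `sqrt(area_scale)` (rigid
#'   superimposition has no scaling freedom, so this is a pure size
#'   asymmetry).
#' @param cell_scale_sd SD of the log-normal per-cell Voronoi weight
#'   perturbation on the left wing (0 = none); perturbs relative cell
#'   areas.
#' @param jitter_sd SD in px of Gaussian jitter of the left wing's Voronoi
#'   seeds (vertex-level shape noise).
#' @param offset_x,offset_y,offset_theta Rigid offset of the left wing
#'   (px, px, radians).
#' @param noise Salt-and-pepper fraction applied to the left image (half
#'   salt, half pepper), pixelwise before binarization.
#' @param blur Gaussian blur sigma in px applied to the left image
#'   (0 = none).
#' @param lloyd_iters Centroidal (Lloyd) relaxation iterations.
#' @return A `wa_synth_config` object.
#' @export
synth_config <- function(seed = 1, n_cells = 25, height = 320, width = 480,
                         vein_width = 3, area_scale = 1, cell_scale_sd = 0,
                         jitter_sd = 0, offset_x = 0, offset_y = 0,
                         offset_theta = 0, noise = 0, blur = 0,
                         lloyd_iters = 20) {
  stopifnot(n_cells >= 10, height >= 64, width >= 64, vein_width >= 2,
            area_scale > 0, cell_scale_sd >= 0, jitter_sd >= 0,
            noise >= 0, noise < 1, blur >= 0)
  structure(as.list(environment()), class = "wa_synth_config")
}

# Blade silhouette: ellipse with a tapering trailing edge toward the tip.
blade_params <- function(height, width) {
  list(cy = height / 2, cx = width / 2, a = 0.40 * width, b = 0.30 * height,
       taper = 0.25)
}

blade_inside <- function(row, col, bp) {
  u <- (col - bp$cx) / bp$a
  beff <- bp$b * (1 - bp$taper * u)
  inside <- beff > 0 & u^2 + ((row - bp$cy) / beff)^2 <= 1
  inside[is.na(inside)] <- FALSE
  inside
}

# Sample seed points inside the blade and relax them toward a centroidal
# Voronoi configuration on a coarse pixel grid.
sample_seeds <- function(config, bp) {
  n <- config$n_cells
  pts <- matrix(numeric(0), 0, 2)
  while (nrow(pts) < n) {
    cand <- cbind(runif(4 * n, 1, config$height), runif(4 * n, 1, config$width))
    cand <- cand[blade_inside(cand[, 1], cand[, 2], bp), , drop = FALSE]
    pts <- rbind(pts, cand)
  }
  seeds <- pts[seq_len(n), , drop = FALSE]
  # Lloyd relaxation on a step-2 subgrid
  rr <- seq(1, config$height, by = 2)
  cc <- seq(1, config$width, by = 2)
  grid <- cbind(rep(rr, times = length(cc)), rep(cc, each = length(rr)))
  grid <- grid[blade_inside(grid[, 1], grid[, 2], bp), , drop = FALSE]
  for (it in seq_len(config$lloyd_iters)) {
    lab <- nearest_match(grid, seeds)$index
    cnt <- tabulate(lab, n)
    rs <- rowsum(grid, lab)
    present <- as.integer(rownames(rs))
    seeds[present, 1] <- rs[, 1] / cnt[present]
    seeds[present, 2] <- rs[, 2] / cnt[present]
  }
  seeds
}

# Rasterize one wing. The base tessellation (seeds, weights, blade) is
# evaluated at inverse-transformed pixel coordinates, so a geometric
# transform of the wing is rendered exactly rather than by resampling.
render_wing <- function(config, seeds, weights, s = 1, theta = 0,
                        tx = 0, ty = 0) {
  H <- config$height; W <- config$width
  bp <- blade_params(H, W)
  rowm <- matrix(seq_len(H), H, W)
  colm <- matrix(seq_len(W), H, W, byrow = TRUE)
  ct <- cos(-theta); st <- sin(-theta)
  dx <- (colm - bp$cx - tx) / s
  dy <- (rowm - bp$cy - ty) / s
  bcol <- bp$cx + ct * dx - st * dy
  brow <- bp$cy + st * dx + ct * dy

  inside <- blade_inside(brow, bcol, bp)
  labels <- matrix(0L, H, W)
  idx <- which(inside)
  if (length(idx)) {
    pts <- cbind(brow[idx], bcol[idx])
    d2 <- outer(rowSums(pts^2), rep(1, nrow(seeds))) +
      outer(rep(1, nrow(pts)), rowSums(seeds^2)) - 2 * pts %*% t(seeds)
    d2 <- sweep(d2, 2, weights, `/`)
    labels[idx] <- max.col(-d2, ties.method = "first")
  }

  edge <- matrix(FALSE, H, W)
  for (off in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
    nb <- shift_mat(labels, off[1], off[2], 0L)
    edge <- edge | (inside & nb != labels)
  }
  dmap <- EBImage::imageData(EBImage::distmap(EBImage::as.Image(!edge)))
  vein <- dmap <= config$vein_width / 2

  pixels <- matrix(1, H, W)
  pixels[inside] <- 0.94
  pixels[vein] <- 0.12

  lab_v <- labels[idx]
  areas <- tabulate(lab_v, nbins = nrow(seeds))
  rr <- ((idx - 1) %% H) + 1; cc <- ((idx - 1) %/% H) + 1
  cent <- matrix(NA_real_, nrow(seeds), 2,
                 dimnames = list(NULL, c("row", "col")))
  rs <- rowsum(cbind(rr, cc), lab_v)
  present <- as.integer(rownames(rs))
  cent[present, 1] <- rs[, 1] / areas[present]
  cent[present, 2] <- rs[, 2] / areas[present]

  # tessellation vertices: 2x2 pixel blocks containing >= 3 distinct
  # regions (outside-blade counting as region 0), clustered
  a11 <- labels[-H, -W]; a12 <- labels[-H, -1]
  a21 <- labels[-1, -W]; a22 <- labels[-1, -1]
  distinct <- 1 +
    (a12 != a11) +
    (a21 != a11 & a21 != a12) +
    (a22 != a11 & a22 != a12 & a22 != a21)
  corner <- matrix(FALSE, H, W)
  corner[-H, -W] <- distinct >= 3 & (a11 + a12 + a21 + a22 > 0)
  vert <- data.frame(row = numeric(0), col = numeric(0))
  if (any(corner)) {
    comp <- cc_label_cpp(corner, 8L)
    cidx <- which(comp > 0)
    cl <- comp[cidx]
    vr <- ((cidx - 1) %% H) + 1 + 0.5
    vc <- ((cidx - 1) %/% H) + 1 + 0.5
    ncl <- max(cl)
    cnt <- tabulate(cl, ncl)
    vert <- data.frame(row = rowsum(vr, cl)[, 1] / cnt,
                       col = rowsum(vc, cl)[, 1] / cnt)
  }

  list(pixels = pixels,
       truth = list(seeds = seeds, weights = weights,
                    cell_areas = areas, cell_centroids = cent,
                    vertices = vert, silhouette_area = sum(inside)))
}

#' Generate a synthetic wing image with ground truth
#'
#' @param config A `wa_synth_config`.
#' @return List with `image` (a `wa_raw`) and `truth` (seeds, exact cell
#'   areas and centroids of the tessellation, tessellation vertices, and
#'   the silhouette area).
#' @export
generate_wing <- function(config = synth_config()) {
  stopifnot(inherits(config, "wa_synth_config"))
  with_seed(config$seed, {
    bp <- blade_params(config$height, config$width)
    seeds <- sample_seeds(config, bp)
    r <- render_wing(config, seeds, rep(1, nrow(seeds)))
    list(image = wa_raw(r$pixels, source_path = "synthetic"),
         truth = r$truth)
  })
}

#' Generate a synthetic left/right wing pair with ground truth
#'
#' The right wing is the unperturbed base render. The left wing applies
#' the configured per-cell weight perturbation, seed jitter, global area
#' scaling and rigid offset, is then mirrored (as a real left wing would
#' be), and finally receives salt-and-pepper noise and Gaussian blur on
#' the intensity image.
#'
#' @param config A `wa_synth_config`.
#' @return List with `left`, `right` (`wa_raw` images; `left` is mirrored)
#'   and `truth` (per-wing tessellation truth, the true rigid offset and
#'   all perturbation parameters).
#' @export
generate_pair <- function(config = synth_config()) {
  stopifnot(inherits(config, "wa_synth_config"))
  with_seed(config$seed, {
    bp <- blade_params(config$height, config$width)
    seeds <- sample_seeds(config, bp)
    right <- render_wing(config, seeds, rep(1, nrow(seeds)))

    n <- nrow(seeds)
    weights_l <- if (config$cell_scale_sd > 0)
      exp(rnorm(n, 0, config$cell_scale_sd)) else rep(1, n)
    seeds_l <- seeds + if (config$jitter_sd > 0)
      matrix(rnorm(2 * n, 0, config$jitter_sd), n, 2) else 0
    left <- render_wing(config, seeds_l, weights_l,
                        s = sqrt(config$area_scale),
                        theta = config$offset_theta,
                        tx = config$offset_x, ty = config$offset_y)
    px <- left$pixels[, rev(seq_len(ncol(left$pixels))), drop = FALSE]
    if (config$noise > 0) {
      k <- round(config$noise * length(px))
      if (k > 0) {
        at <- sample(length(px), k)
        half <- k %/% 2
        px[at[seq_len(half)]] <- 0            # pepper
        if (k > half) px[at[(half + 1):k]] <- 1  # salt
      }
    }
    if (config$blur > 0) {
      px <- EBImage::imageData(EBImage::gblur(EBImage::as.Image(px),
                                              sigma = config$blur))
      px[px < 0] <- 0; px[px > 1] <- 1
    }
    list(left = wa_raw(px, source_path = "synthetic-left"),
         right = wa_raw(right$pixels, source_path = "synthetic-right"),
         truth = list(right = right$truth, left = left$truth,
                      left_mirrored = TRUE,
                      transform = c(x = config$offset_x, y = config$offset_y,
                                    theta = config$offset_theta),
                      area_scale = config$area_scale,
                      cell_scale_sd = config$cell_scale_sd,
                      jitter_sd = config$jitter_sd,
                      noise = config$noise, blur = config$blur))
  })
}

#' Write a synthetic pair to disk
#'
#' Writes `left.png`, `right.png` and `truth.json` into `dir`.
#'
#' @param pair Output of [generate_pair()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the three file paths.
#' @export
write_pair <- function(pair, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lp <- file.path(dir, "left.png"); rp <- file.path(dir, "right.png")
  tp <- file.path(dir, "truth.json")
  EBImage::writeImage(EBImage::as.Image(t(pair$left$pixels)), lp)
  EBImage::writeImage(EBImage::as.Image(t(pair$right$pixels)), rp)
  jsonlite::write_json(pair$truth, tp, auto_unbox = TRUE, digits = NA)
  invisible(c(lp, rp, tp))
}
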