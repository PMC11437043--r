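# Rigid superimposition (translation + rotation, deliberately no scaling)
# of two segmented wings, and centroid-based correspondence matching.

#' Construct a rigid transform
#'
#' @param x Column translation (px).
#' @param y Row translation (px).
#' @param theta Rotation angle in radians, applied about the moving wing's
#'   outline centroid. Positive theta rotates from the +x (column) axis
#'   toward the +y (row) axis.
#' @return A `wa_transform` object.
#' @export
rigid_transform <- function(x = 0, y = 0, theta = 0) {
  stopifnot(is.numeric(x), is.numeric(y), is.numeric(theta))
  structure(list(x = as.numeric(x), y = as.numeric(y),
                 theta = as.numeric(theta)),
            class = "wa_transform")
}

# Centroid of the outline polyline (mean of its vertices).
outline_centroid <- function(geometry) {
  colMeans(geometry$outline)
}

# Rotate pts (n x 2, (row, col)) by theta about pivot, then translate.
transform_points <- function(pts, t, pivot) {
  dy <- pts[, 1] - pivot[1]; dx <- pts[, 2] - pivot[2]
  ct <- cos(t$theta); st <- sin(t$theta)
  cbind(pivot[1] + st * dx + ct * dy + t$y,
        pivot[2] + ct * dx - st * dy + t$x)
}

#' Apply a rigid transform to a wing geometry
#'
#' Outline points, cell centroids and junctions are rotated by `theta`
#' about the outline centroid and then translated by `(x, y)`. All scalar
#' metrics (areas, lengths, circularities, counts) are unchanged.
#'
#' @param geometry A `wa_geometry` object.
#' @param t A `wa_transform`.
#' @return The transformed `wa_geometry`.
#' @export
apply_transform <- function(geometry, t) {
  stopifnot(inherits(geometry, "wa_geometry"), inherits(t, "wa_transform"))
  pivot <- outline_centroid(geometry)
  geometry$outline <- transform_points(geometry$outline, t, pivot)
  if (nrow(geometry$cells)) {
    p <- transform_points(cbind(geometry$cells$centroid_row,
                                geometry$cells$centroid_col), t, pivot)
    geometry$cells$centroid_row <- p[, 1]
    geometry$cells$centroid_col <- p[, 2]
  }
  if (nrow(geometry$junctions)) {
    p <- transform_points(cbind(geometry$junctions$row,
                                geometry$junctions$col), t, pivot)
    geometry$junctions$row <- p[, 1]
    geometry$junctions$col <- p[, 2]
  }
  geometry
}

#' Translation aligning the outline centroids
#'
#' Returns the pure translation `(x, y, theta = 0)` that moves the moving
#' wing's outline centroid onto the reference wing's. This is the
#' initialization center of the PSO search.
#'
#' @param ref,moving `wa_geometry` objects.
#' @return A `wa_transform`.
#' @export
align_centroids <- function(ref, moving) {
  cr <- outline_centroid(ref); cm <- outline_centroid(moving)
  rigid_transform(x = cr[2] - cm[2], y = cr[1] - cm[1], theta = 0)
}

#' Mean outline distance under a transform
#'
#' Both outlines are resampled to `n` points at equal arc length. The
#' one-directional objective is the mean, over the moving wing's resampled
#' points after applying `t`, of the distance to the nearest resampled
#' reference point; the symmetric version averages both directions and is
#' the reported outline-distance metric.
#'
#' @param ref,moving `wa_geometry` objects with non-degenerate outlines.
#' @param t A `wa_transform` applied to the moving wing.
#' @param n Number of resampled points per outline (default 200).
#' @param symmetric Average of both directions (default `FALSE`, the
#'   one-directional objective used inside the PSO).
#' @return Mean distance in pixels.
#' @export
outline_objective <- function(ref, moving, t = rigid_transform(), n = 200,
                              symmetric = FALSE) {
  rp <- resample_closed(ref$outline, n)
  mp <- resample_closed(moving$outline, n)
  mp <- transform_points(mp, t, outline_centroid(moving))
  d1 <- mean(nearest_dist(mp, rp))
  if (!symmetric) return(d1)
  (d1 + mean(nearest_dist(rp, mp))) / 2
}

#' PSO configuration
#'
#' Defaults are the standard configuration of the automated
#' superimposition: 3 variables (x, y, theta), 40 iterations, 30
#' particles, inertia weight 1 damped by 0.95 per iteration, and
#' cognitive/social coefficients 1.2.
#'
#' @param max_iterations,n_particles,w,w_damp,c1,c2 PSO parameters.
#' @param seed Integer seed for reproducible runs (default 0); `NULL`
#'   leaves the RNG state alone.
#' @param bounds Optional 3 x 2 matrix of (low, high) absolute bounds for
#'   (x, y, theta); by default x and y span +/- width/4 around the
#'   centroid-aligning translation and theta spans +/- 30 degrees.
#' @param n_points Outline resampling resolution (default 200).
#' @return A `wa_pso_config` object.
#' @export
pso_config <- function(max_iterations = 40, n_particles = 30, w = 1,
                       w_damp = 0.95, c1 = 1.2, c2 = 1.2, seed = 0,
                       bounds = NULL, n_points = 200) {
  stopifnot(max_iterations >= 1, n_particles >= 2, w > 0, w_damp > 0,
            c1 > 0, c2 > 0, n_points >= 10)
  structure(list(n_variables = 3L, max_iterations = as.integer(max_iterations),
                 n_particles = as.integer(n_particles), w = w, w_damp = w_damp,
                 c1 = c1, c2 = c2, seed = seed, bounds = bounds,
                 n_points = as.integer(n_points)),
            class = "wa_pso_config")
}

#' Superimpose two wings by particle swarm optimization
#'
#' Global-best PSO over (x, y, theta) minimizing the one-directional mean
#' outline distance. Velocities update as
#' `v <- w * v + c1 * r1 * (pbest - pos) + c2 * r2 * (gbest - pos)` with
#' `r1, r2 ~ U(0, 1)` per dimension; positions are clamped to the bounds;
#' `w` is multiplied by `w_damp` each iteration. Particles start uniformly
#' within the bounds, which are centered on the centroid-aligning
#' translation; initial velocities are zero.
#'
#' @param ref,moving `wa_geometry` objects.
#' @param config A `wa_pso_config`.
#' @return List with `transform` (best `wa_transform`), `objective` (its
#'   one-directional mean outline distance), `history` (per-iteration best
#'   objective, length `max_iterations`, non-increasing), `n_particles`,
#'   `iterations`.
#' @export
pso_superimpose <- function(ref, moving, config = pso_config()) {
  stopifnot(inherits(config, "wa_pso_config"))
  n <- config$n_points
  rp <- resample_closed(ref$outline, n)
  mp0 <- resample_closed(moving$outline, n)
  pivot <- outline_centroid(moving)
  t0 <- align_centroids(ref, moving)

  bounds <- config$bounds
  if (is.null(bounds)) {
    wimg <- if (!is.null(ref$dims)) ref$dims[2] else diff(range(ref$outline[, 2]))
    bounds <- rbind(x = c(t0$x - wimg / 4, t0$x + wimg / 4),
                    y = c(t0$y - wimg / 4, t0$y + wimg / 4),
                    theta = c(-30, 30) * pi / 180)
  }
  bounds <- matrix(as.numeric(bounds), 3, 2)
  if (any(bounds[, 1] >= bounds[, 2]))
    stop("invalid PSO bounds: low must be < high for every variable")

  obj <- function(pos) {
    t <- rigid_transform(pos[1], pos[2], pos[3])
    mean(nearest_dist(transform_points(mp0, t, pivot), rp))
  }

  with_seed(config$seed, {
    np <- config$n_particles
    pos <- sapply(1:3, function(j) runif(np, bounds[j, 1], bounds[j, 2]))
    vel <- matrix(0, np, 3)
    cost <- apply(pos, 1, obj)
    pbest <- pos; pbest_cost <- cost
    g <- which.min(cost)
    gbest <- pos[g, ]; gbest_cost <- cost[g]
    history <- numeric(config$max_iterations)
    w <- config$w
    for (it in seq_len(config$max_iterations)) {
      r1 <- matrix(runif(np * 3), np, 3)
      r2 <- matrix(runif(np * 3), np, 3)
      vel <- w * vel + config$c1 * r1 * (pbest - pos) +
        config$c2 * r2 * (sweep(pos, 2, gbest, function(p, g) g - p))
      pos <- pos + vel
      for (j in 1:3) pos[, j] <- pmin(pmax(pos[, j], bounds[j, 1]), bounds[j, 2])
      cost <- apply(pos, 1, obj)
      imp <- cost < pbest_cost
      pbest[imp, ] <- pos[imp, ]; pbest_cost[imp] <- cost[imp]
      g <- which.min(pbest_cost)
      if (pbest_cost[g] < gbest_cost) {
        gbest <- pbest[g, ]; gbest_cost <- pbest_cost[g]
      }
      history[it] <- gbest_cost
      w <- w * config$w_damp
    }
    list(transform = rigid_transform(gbest[1], gbest[2], gbest[3]),
         objective = gbest_cost, history = history,
         n_particles = np, iterations = config$max_iterations)
  })
}

# Nearest-centroid matching between two point tables.
match_points <- function(ref_pts, ref_ids, target_pts, target_ids) {
  if (nrow(ref_pts) == 0 || nrow(target_pts) == 0)
    return(data.frame(ref_id = integer(0), target_id = integer(0),
                      distance = numeric(0)))
  m <- nearest_match(ref_pts, target_pts)
  data.frame(ref_id = ref_ids, target_id = target_ids[m$index],
             distance = m$distance)
}

#' Match cells between superimposed wings
#'
#' For each reference cell, the target cell with the minimum centroid
#' distance is recorded. A target cell may be the nearest neighbor of
#' several reference cells; the bidirectional protocol (running the match
#' once per reference direction) is applied at the pair level rather than
#' forcing an injective assignment.
#'
#' @param ref,target `wa_geometry` objects, already superimposed.
#' @return Data frame `ref_id, target_id, distance` with one row per
#'   reference cell.
#' @export
match_cells <- function(ref, target) {
  if (nrow(target$cells) == 0) {
    warning("target wing has no cells; empty correspondence")
    return(data.frame(ref_id = integer(0), target_id = integer(0),
                      distance = numeric(0)))
  }
  match_points(cbind(ref$cells$centroid_row, ref$cells$centroid_col),
               ref$cells$cell_id,
               cbind(target$cells$centroid_row, target$cells$centroid_col),
               target$cells$cell_id)
}

#' Match junctions between superimposed wings
#'
#' Same nearest-neighbor protocol as [match_cells()], on junction
#' positions.
#'
#' @param ref,target `wa_geometry` objects, already superimposed.
#' @return Data frame `ref_id, target_id, distance`.
#' @export
match_junctions <- function(ref, target) {
  if (nrow(target$junctions) == 0) {
    warning("target wing has no junctions; empty correspondence")
    return(data.frame(ref_id = integer(0), target_id = integer(0),
                      distance = numeric(0)))
  }
  match_points(cbind(ref$junctions$row, ref$junctions$col),
               ref$junctions$junction_id,
               cbind(target$junctions$row, target$junctions$col),
               target$junctions$junction_id)
}

#' @export
print.wa_transform <- function(x, ...) {
  cat("<wa_transform> x = ", signif(x$x, 6), ", y = ", signif(x$y, 6),
      ", theta = ", signif(x$theta * 180 / pi, 6), " deg\n", sep = "")
  invisible(x)
}
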