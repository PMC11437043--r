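# Asymmetry metrics for a superimposed, matched wing pair.

CELL_METRICS <- c("area", "length", "width", "circularity")

#' Ordinary least squares of target on reference
#'
#' Fits `target = intercept + slope * ref` and reports the coefficient of
#' determination. For a perfectly symmetric pair the fit is the identity
#' line with r-squared 1.
#'
#' @param ref,target Equal-length numeric vectors (>= 2 values, ordered by
#'   the correspondence).
#' @return List with `slope`, `intercept`, `r2`.
#' @export
regression <- function(ref, target) {
  if (length(ref) != length(target) || length(ref) < 2)
    stop("regression needs two equal-length vectors with >= 2 values")
  if (var(ref) == 0) stop("degenerate regression: zero variance in reference")
  slope <- sum((ref - mean(ref)) * (target - mean(target))) /
    sum((ref - mean(ref))^2)
  intercept <- mean(target) - slope * mean(ref)
  ss_tot <- sum((target - mean(target))^2)
  ss_res <- sum((target - intercept - slope * ref)^2)
  r2 <- if (ss_tot == 0) as.numeric(ss_res == 0) else 1 - ss_res / ss_tot
  list(slope = slope, intercept = intercept, r2 = max(0, min(1, r2)))
}

#' Normalized root mean square error
#'
#' RMSE of `target - ref`, divided by the reference range
#' `max(ref) - min(ref)`. Range normalization makes the four cell metrics
#' (area, length, width, circularity) comparable despite their different
#' units, and is invariant under a common positive rescaling of both
#' vectors.
#'
#' @param ref,target Equal-length numeric vectors (>= 2 values).
#' @return Non-negative scalar.
#' @export
nrmse <- function(ref, target) {
  if (length(ref) != length(target) || length(ref) < 2)
    stop("nrmse needs two equal-length vectors with >= 2 values")
  rng <- max(ref) - min(ref)
  if (rng == 0) stop("zero normalization range: constant reference vector")
  sqrt(mean((target - ref)^2)) / rng
}

#' Distance statistics per correspondence category
#'
#' Arithmetic mean and population standard deviation (divisor n) of the
#' matched centroid distances, junction distances and resampled outline
#' distances, in scaled units. Categories with no pairs are dropped with a
#' warning.
#'
#' @param cell_distances,junction_distances,outline_distances Numeric
#'   vectors of per-pair distances (any may be empty).
#' @return Data frame `category, n, mean, sd`.
#' @export
distance_stats <- function(cell_distances = numeric(0),
                           junction_distances = numeric(0),
                           outline_distances = numeric(0)) {
  cats <- list(centroid = cell_distances, junction = junction_distances,
               outline = outline_distances)
  keep <- vapply(cats, length, 1L) > 0
  if (!all(keep))
    warning("no distances for: ", paste(names(cats)[!keep], collapse = ", "))
  cats <- cats[keep]
  data.frame(category = names(cats),
             n = vapply(cats, length, 1L),
             mean = vapply(cats, mean, 1),
             sd = vapply(cats, pop_sd, 1),
             row.names = NULL)
}

#' Signed count and whole-wing size differences
#'
#' Signed `wing1 - wing2` differences of cell and junction counts and of
#' the whole-wing area, length, width and perimeter.
#'
#' @param wing1,wing2 `wa_geometry` objects.
#' @return Named numeric vector with elements `delta_n_cells`,
#'   `delta_n_junctions`, `delta_wing_area`, `delta_wing_length`,
#'   `delta_wing_width`, `delta_wing_perimeter`.
#' @export
count_and_size_deltas <- function(wing1, wing2) {
  c(delta_n_cells = wing1$n_cells - wing2$n_cells,
    delta_n_junctions = wing1$n_junctions - wing2$n_junctions,
    delta_wing_area = wing1$wing_area - wing2$wing_area,
    delta_wing_length = wing1$wing_length - wing2$wing_length,
    delta_wing_width = wing1$wing_width - wing2$wing_width,
    delta_wing_perimeter = wing1$wing_perimeter - wing2$wing_perimeter)
}

#' Percentage deviation from a reference measurement
#'
#' `100 * |ref - test| / ref`, the accuracy criterion used to benchmark
#' one measurement pipeline against another on the same objects.
#'
#' @param result_ref Reference value (nonzero).
#' @param result_test Value under test.
#' @return Percentage deviation.
#' @export
accuracy_percent <- function(result_ref, result_test) {
  if (any(result_ref == 0)) stop("reference result must be nonzero")
  100 * abs(result_ref - result_test) / result_ref
}

# Regression + NRMSE rows for one reference direction.
direction_metrics <- function(ref_cells, target_cells, corr, direction) {
  out <- lapply(CELL_METRICS, function(m) {
    rv <- ref_cells[[m]][match(corr$ref_id, ref_cells$cell_id)]
    tv <- target_cells[[m]][match(corr$target_id, target_cells$cell_id)]
    if (length(rv) < 2 || var(rv) == 0 || (max(rv) - min(rv)) == 0) {
      warning("too few matched cells or degenerate values for metric ", m)
      return(data.frame(direction = direction, metric = m, slope = NA_real_,
                        intercept = NA_real_, r2 = NA_real_, nrmse = NA_real_))
    }
    fit <- regression(rv, tv)
    data.frame(direction = direction, metric = m, slope = fit$slope,
               intercept = fit$intercept, r2 = fit$r2,
               nrmse = nrmse(rv, tv))
  })
  do.call(rbind, out)
}

#' Evaluate all asymmetry metrics for a wing pair
#'
#' Applies the rigid transform to `wing2`, matches cells and junctions in
#' both reference directions (first wing 1 as reference, then wing 2),
#' computes regression and NRMSE for area, length, width and circularity
#' in each direction, distance statistics for centroids, junctions and the
#' resampled outlines, and signed count/size deltas.
#'
#' @param wing1,wing2 Segmented `wa_geometry` objects.
#' @param transform `wa_transform` superimposing wing 2 onto wing 1
#'   (default identity).
#' @param n_points Outline resampling resolution for outline distances.
#' @return A `wa_pair_result`: list with `metrics` (data frame: direction,
#'   metric, slope, intercept, r2, nrmse), `distances` (data frame:
#'   direction, category, n, mean, sd), `deltas`, `outline_mean_symmetric`,
#'   `matches` (the four correspondence tables) and `transform`.
#' @export
evaluate_pair <- function(wing1, wing2, transform = rigid_transform(),
                          n_points = 200) {
  stopifnot(inherits(wing1, "wa_geometry"), inherits(wing2, "wa_geometry"))
  w2 <- apply_transform(wing2, transform)

  cor1 <- match_cells(wing1, w2)
  cor2 <- match_cells(w2, wing1)
  jun1 <- match_junctions(wing1, w2)
  jun2 <- match_junctions(w2, wing1)

  metrics <- rbind(direction_metrics(wing1$cells, w2$cells, cor1, 1L),
                   direction_metrics(w2$cells, wing1$cells, cor2, 2L))

  rp1 <- resample_closed(wing1$outline, n_points)
  rp2 <- resample_closed(w2$outline, n_points)
  s <- wing1$scale %||% 1
  out12 <- nearest_dist(rp1, rp2) * s
  out21 <- nearest_dist(rp2, rp1) * s

  d1 <- distance_stats(cor1$distance * s, jun1$distance * s, out12)
  d2 <- distance_stats(cor2$distance * s, jun2$distance * s, out21)
  distances <- rbind(cbind(direction = 1L, d1), cbind(direction = 2L, d2))

  structure(list(metrics = metrics,
                 distances = distances,
                 deltas = count_and_size_deltas(wing1, wing2),
                 outline_mean_symmetric = mean(c(out12, out21)),
                 matches = list(cells_ref1 = cor1, cells_ref2 = cor2,
                                junctions_ref1 = jun1, junctions_ref2 = jun2),
                 transform = transform),
            class = "wa_pair_result")
}

#' @export
print.wa_pair_result <- function(x, ...) {
  cat("<wa_pair_result>\n")
  cat("  transform: x =", signif(x$transform$x, 5),
      "y =", signif(x$transform$y, 5),
      "theta =", signif(x$transform$theta * 180 / pi, 5), "deg\n")
  m <- x$metrics[x$metrics$direction == 1, ]
  for (i in seq_len(nrow(m)))
    cat(sprintf("  %-12s r2 = %.4f  nrmse = %.4f  slope = %.4f\n",
                m$metric[i], m$r2[i], m$nrmse[i], m$slope[i]))
  cat("  mean symmetric outline distance:",
      signif(x$outline_mean_symmetric, 5), "\n")
  cat("  delta cells:", x$deltas[["delta_n_cells"]],
      " delta junctions:", x$deltas[["delta_n_junctions"]], "\n")
  invisible(x)
}
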