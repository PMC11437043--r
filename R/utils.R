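# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Shift a matrix by (dr, dc), padding with `fill`.
shift_mat <- function(m, dr, dc, fill = 0L) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- seq_len(nr) - dr; cs <- seq_len(nc) - dc
  rk <- rs >= 1 & rs <= nr; ck <- cs >= 1 & cs <= nc
  out[rk, ck] <- m[rs[rk], cs[ck]]
  out
}

# Maximum pairwise Euclidean distance between points (n x 2 matrix),
# computed exactly via the convex hull (the diameter is attained on it).
max_pairwise_dist <- function(pts) {
  if (nrow(pts) < 2) return(0)
  h <- grDevices::chull(pts[, 2], pts[, 1])
  max(stats::dist(pts[h, , drop = FALSE]))
}

# Population standard deviation (divisor n, not n - 1).
pop_sd <- function(x) {
  if (length(x) == 0) return(NA_real_)
  sqrt(mean((x - mean(x))^2))
}

# Index (into rows of b) of the nearest row of b for each row of a,
# together with the distance. The argmin is found on the expanded squared
# distance matrix; the reported distance is recomputed directly so that
# identical points give exactly 0 (no catastrophic cancellation).
nearest_match <- function(a, b) {
  d2 <- outer(rowSums(a^2), rep(1, nrow(b))) +
    outer(rep(1, nrow(a)), rowSums(b^2)) - 2 * a %*% t(b)
  j <- max.col(-d2, ties.method = "first")
  list(index = j,
       distance = sqrt((a[, 1] - b[j, 1])^2 + (a[, 2] - b[j, 2])^2))
}

# For each row of `a`, the Euclidean distance to the nearest row of `b`.
nearest_dist <- function(a, b) nearest_match(a, b)$distance

# Resample a closed polyline (n x 2, first point not repeated) to `n` points
# equally spaced in arc length, starting at the first vertex.
resample_closed <- function(pts, n) {
  if (nrow(pts) < 3) stop("degenerate outline: fewer than 3 points")
  closed <- rbind(pts, pts[1, ])
  seg <- sqrt(rowSums(diff(closed)^2))
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  if (total <= 0) stop("degenerate outline: zero length")
  s <- seq(0, total, length.out = n + 1)[seq_len(n)]
  i <- findInterval(s, cum, rightmost.closed = TRUE)
  i[i >= length(cum)] <- length(cum) - 1
  frac <- (s - cum[i]) / pmax(seg[i], .Machine$double.eps)
  closed[i, , drop = FALSE] + frac * (closed[i + 1, , drop = FALSE] - closed[i, , drop = FALSE])
}
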