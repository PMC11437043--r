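# Independent oracles used across the suite. These deliberately use naive
# algorithms (queues, double loops, direct formulas) so they share no code
# with the implementation they check.

# Breadth-first flood fill over the 8-connected TRUE component of seed.
bfs_flood <- function(mask, seed) {
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  queue <- list(seed)
  seen[seed[1], seed[2]] <- TRUE
  out <- list()
  while (length(queue)) {
    p <- queue[[1]]; queue <- queue[-1]
    out[[length(out) + 1]] <- p
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      r <- p[1] + dr; c <- p[2] + dc
      if (r < 1 || r > nr || c < 1 || c > nc) next
      if (mask[r, c] && !seen[r, c]) {
        seen[r, c] <- TRUE
        queue[[length(queue) + 1]] <- c(r, c)
      }
    }
  }
  do.call(rbind, out)
}

# Sort pixel coordinate rows for set comparison.
sort_pixels <- function(m) m[order(m[, 1], m[, 2]), , drop = FALSE]

# Count connected components by repeated BFS (conn = 8 or 4), independent
# of the package's labeling kernel.
count_components <- function(mask, conn = 8) {
  remaining <- mask
  n <- 0
  while (any(remaining)) {
    seed <- which(remaining, arr.ind = TRUE)[1, ]
    comp <- if (conn == 8) bfs_flood(remaining, seed) else {
      # 4-connected variant
      nr <- nrow(remaining); nc <- ncol(remaining)
      seen <- matrix(FALSE, nr, nc)
      queue <- list(seed); seen[seed[1], seed[2]] <- TRUE
      out <- list()
      while (length(queue)) {
        p <- queue[[1]]; queue <- queue[-1]
        out[[length(out) + 1]] <- p
        for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
          r <- p[1] + d[1]; c <- p[2] + d[2]
          if (r < 1 || r > nr || c < 1 || c > nc) next
          if (remaining[r, c] && !seen[r, c]) {
            seen[r, c] <- TRUE
            queue[[length(queue) + 1]] <- c(r, c)
          }
        }
      }
      do.call(rbind, out)
    }
    remaining[comp] <- FALSE
    n <- n + 1
  }
  n
}

# Crossing number of a 3 x 3 neighborhood pattern, by explicit walk around
# the cyclic neighbor sequence N, NE, E, SE, S, SW, W, NW.
oracle_crossing_number <- function(nbrs) {
  s <- c(nbrs, nbrs[1])
  sum(s[-length(s)] == 0 & s[-1] == 1)
}

# Exhaustive nearest neighbor: for each row of a, scan all rows of b.
oracle_nearest <- function(a, b) {
  t(apply(a, 1, function(p) {
    d <- sqrt((b[, 1] - p[1])^2 + (b[, 2] - p[2])^2)
    c(which.min(d), min(d))
  }))
}

# Build a wa_binary directly from a logical matrix (TRUE = membrane).
as_binary <- function(mask, scale = NULL) {
  structure(list(mask = mask, threshold = 0.5, mirrored = FALSE,
                 scale = scale), class = "wa_binary")
}

# Minimal hand-built geometry for metric-path tests: cells on a grid.
fake_geometry <- function(cells, outline = NULL) {
  if (is.null(outline))
    outline <- cbind(c(0, 0, 100, 100), c(0, 100, 100, 0))
  structure(list(cells = cells, cell_boundaries = list(),
                 outline = outline,
                 junctions = data.frame(junction_id = integer(0),
                                        row = numeric(0), col = numeric(0)),
                 wing_area = 1, wing_length = 1, wing_width = 1,
                 wing_perimeter = 1, n_cells = nrow(cells), n_junctions = 0L,
                 scale = 1, dims = c(100L, 100L)),
            class = "wa_geometry")
}
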