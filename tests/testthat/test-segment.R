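test_that("grow_region floods a block and records its dark boundary", {
  mask <- matrix(FALSE, 5, 5)
  mask[2:4, 2:4] <- TRUE
  cell <- grow_region(as_binary(mask), c(3, 3))
  expect_equal(cell$area, 9)
  expect_equal(nrow(cell$boundary), 16)
  ring <- expand.grid(row = 1:5, col = 1:5)
  ring <- ring[!(ring$row %in% 2:4 & ring$col %in% 2:4), ]
  expect_equal(sort_pixels(cell$boundary),
               unname(as.matrix(ring[order(ring$row, ring$col), ])),
               ignore_attr = TRUE)
  expect_error(grow_region(as_binary(mask), c(1, 1)), "foreground")
  expect_error(grow_region(as_binary(mask), c(99, 1)), "bounds")
})

test_that("growing never crosses to a disconnected component", {
  mask <- matrix(FALSE, 7, 9)
  mask[2:3, 2:3] <- TRUE
  mask[5:6, 6:8] <- TRUE
  cell <- grow_region(as_binary(mask), c(2, 2))
  expect_equal(cell$area, 4)
  expect_true(all(cell$interior[, 2] <= 3))
})

test_that("region growing matches a BFS flood-fill oracle on random masks", {
  set.seed(42)
  for (i in 1:25) {
    mask <- matrix(runif(15 * 15) > 0.45, 15, 15)
    seeds <- which(mask, arr.ind = TRUE)
    if (nrow(seeds) == 0) next
    seed <- seeds[sample(nrow(seeds), 1), ]
    cell <- grow_region(as_binary(mask), seed)
    expect_equal(sort_pixels(cell$interior),
                 sort_pixels(bfs_flood(mask, seed)),
                 ignore_attr = TRUE)
  }
})

test_that("segment_all recovers generator ground truth and bookkeeping", {
  fx <- fix_wing()
  g <- fx$geom
  expect_equal(g$n_cells, length(fx$truth$cell_areas))
  # wing area exceeds the cell total exactly by the vein pixels inside
  b <- binarize(fx$raw)
  sil <- extract_outline(b)$silhouette
  dark_inside <- sum(sil & !b$mask)
  light_small <- sum(sil & b$mask) - sum(g$cells$area)
  expect_equal(g$wing_area - sum(g$cells$area), dark_inside + light_small)
  expect_gte(g$wing_area, sum(g$cells$area))
  # every centroid strictly inside the outline bounding box
  expect_true(all(g$cells$centroid_row > min(g$outline[, 1]) &
                    g$cells$centroid_row < max(g$outline[, 1])))
  # discovery order gives sequential ids
  expect_equal(g$cells$cell_id, seq_len(g$n_cells))
})

test_that("an all-light image yields zero cells, not an error", {
  b <- as_binary(matrix(TRUE, 12, 12))
  g <- suppressWarnings(segment_all(b, junctions = FALSE))
  expect_equal(g$n_cells, 0L)
  expect_error(segment_all(as_binary(matrix(FALSE, 12, 12)), junctions = FALSE),
               "empty image")
})

test_that("segmentation metrics are invariant under mirroring", {
  fx <- fix_wing()
  gm <- segment_all(mirror_horizontal(binarize(fx$raw)), junctions = FALSE)
  g <- fx$geom
  for (m in c("area", "length", "width", "circularity", "perimeter"))
    expect_equal(sort(gm$cells[[m]]), sort(g$cells[[m]]), tolerance = 1e-12)
  expect_equal(gm$wing_area, g$wing_area)
  expect_equal(gm$wing_perimeter, g$wing_perimeter, tolerance = 1e-12)
})

test_that("digital disk and square morphometrics approach analytic values", {
  g <- suppressWarnings(segment_all(disk_binary(30), junctions = FALSE))
  expect_equal(g$n_cells, 1L)
  expect_lt(abs(g$cells$area - pi * 30^2) / (pi * 30^2), 0.02)
  expect_gt(g$cells$circularity, 0.85)
  expect_lt(g$cells$circularity, 1.15)
  expect_gt(g$cells$length, 59)   # boundary-ring diameter of a 2r disk
  expect_lt(g$cells$length, 64)

  mask <- matrix(FALSE, 60, 60)
  mask[11:50, 11:50] <- TRUE
  gs <- suppressWarnings(segment_all(as_binary(mask), junctions = FALSE))
  expect_equal(gs$cells$area, 1600)
  expect_equal(gs$cells$circularity, pi / 4, tolerance = 0.1)
})

test_that("extract_outline traces the solid silhouette", {
  mask <- matrix(TRUE, 14, 14)          # light background
  mask[3:12, 3:12] <- FALSE             # dark 10x10 block = silhouette
  out <- extract_outline(as_binary(mask))
  expect_equal(out$wing_area, 100)
  expect_equal(nrow(out$outline), 36)   # border pixels of a 10x10 square
  expect_equal(out$wing_perimeter, 36)
  # interior hole is ignored: carve a light hole inside the block
  mask2 <- mask
  mask2[6:8, 6:8] <- TRUE
  out2 <- extract_outline(as_binary(mask2))
  expect_equal(out2$wing_area, 100)
  expect_equal(nrow(out2$outline), 36)
})
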