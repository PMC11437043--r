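test_that("apply_transform honors identity, periodicity and inverses", {
  g <- fix_wing()$geom
  id <- apply_transform(g, rigid_transform())
  expect_equal(id$outline, g$outline)
  expect_equal(id$cells$centroid_col, g$cells$centroid_col)

  full <- apply_transform(g, rigid_transform(theta = 2 * pi))
  expect_equal(full$outline, g$outline, tolerance = 1e-9)

  fwd <- apply_transform(g, rigid_transform(x = 3, y = -2))
  back <- apply_transform(fwd, rigid_transform(x = -3, y = 2))
  expect_equal(back$outline, g$outline, tolerance = 1e-9)
  # metrics untouched by any transform
  rot <- apply_transform(g, rigid_transform(5, -4, 0.3))
  expect_equal(rot$cells$area, g$cells$area)
  expect_equal(rot$wing_perimeter, g$wing_perimeter)
})

test_that("outline objective is zero at self and bounded by a translation", {
  g <- fix_wing()$geom
  expect_lt(outline_objective(g, g), 1e-6)
  d <- 7
  expect_lte(outline_objective(g, g, rigid_transform(x = d)), d + 1e-9)
  disk <- suppressWarnings(segment_all(disk_binary(25), junctions = FALSE))
  expect_lte(outline_objective(disk, disk, rigid_transform(y = 4)), 4 + 1e-9)
  expect_error(
    outline_objective(fake_geometry(fix_wing()$geom$cells,
                                    outline = cbind(1:2, 1:2)), g),
    "degenerate")
})

test_that("outline objective equals a brute-force all-pairs oracle", {
  set.seed(11)
  for (trial in 1:20) {
    mk <- function() {
      ang <- sort(runif(12, 0, 2 * pi))
      rad <- runif(12, 10, 30)
      fake_geometry(data.frame(cell_id = integer(0)),
                    outline = cbind(50 + rad * sin(ang), 50 + rad * cos(ang)))
    }
    a <- mk(); b <- mk()
    t <- rigid_transform(runif(1, -5, 5), runif(1, -5, 5), runif(1, -0.3, 0.3))
    got <- outline_objective(a, b, t, n = 60)
    rp <- wingasym:::resample_closed(a$outline, 60)
    mp <- wingasym:::transform_points(wingasym:::resample_closed(b$outline, 60),
                                      t, colMeans(b$outline))
    want <- mean(apply(mp, 1, function(p)
      min(sqrt((rp[, 1] - p[1])^2 + (rp[, 2] - p[2])^2))))
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("centroid alignment recovers a pure offset", {
  g <- fix_wing()$geom
  expect_equal(unlist(align_centroids(g, g)[c("x", "y", "theta")]),
               c(x = 0, y = 0, theta = 0))
  moved <- apply_transform(g, rigid_transform(x = 10, y = 5))
  t <- align_centroids(g, moved)
  expect_equal(c(t$x, t$y), c(-10, -5), tolerance = 1e-9)
  aligned <- apply_transform(moved, t)
  expect_lt(sum(abs(colMeans(aligned$outline) - colMeans(g$outline))), 1e-9)
})

test_that("PSO runs the configured swarm and is reproducible", {
  g <- fix_wing()$geom
  fit <- pso_superimpose(g, g, pso_config(seed = 5))
  expect_equal(fit$iterations, 40L)
  expect_equal(fit$n_particles, 30L)
  expect_length(fit$history, 40)
  expect_false(is.unsorted(rev(fit$history)))      # non-increasing
  expect_lt(fit$objective, 0.5)                    # self-alignment
  fit2 <- pso_superimpose(g, g, pso_config(seed = 5))
  expect_identical(unlist(fit$transform), unlist(fit2$transform))
  expect_identical(fit$history, fit2$history)
  expect_error(pso_superimpose(g, g, pso_config(bounds = cbind(1, -1))),
               "bounds")
})

test_that("matching is idempotent, exhaustive and allows shared targets", {
  g <- fix_wing()$geom
  m <- match_cells(g, g)
  expect_equal(m$ref_id, m$target_id)
  expect_true(all(m$distance < 1e-6))

  set.seed(9)
  mkg <- function(n) {
    fake_geometry(data.frame(cell_id = seq_len(n),
                             centroid_row = runif(n, 0, 100),
                             centroid_col = runif(n, 0, 100),
                             area = runif(n, 10, 20), length = runif(n, 2, 9),
                             width = runif(n, 1, 5),
                             circularity = runif(n, 0.5, 1),
                             perimeter = runif(n, 5, 30)))
  }
  ref <- mkg(300); tgt <- mkg(320)
  m2 <- match_cells(ref, tgt)
  expect_equal(nrow(m2), 300)                      # extra target cells ignored
  expect_gte(320 - length(unique(m2$target_id)), 20)
  for (trial in 1:5) {
    a <- mkg(25); b <- mkg(31)
    got <- match_cells(a, b)
    want <- oracle_nearest(cbind(a$cells$centroid_row, a$cells$centroid_col),
                           cbind(b$cells$centroid_row, b$cells$centroid_col))
    expect_equal(got$target_id, as.integer(want[, 1]))
    expect_equal(got$distance, want[, 2], tolerance = 1e-12)
  }
  expect_warning(match_cells(ref, mkg(0)), "no cells")
})
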