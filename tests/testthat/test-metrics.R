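test_that("regression reproduces exact linear relations and the OLS oracle", {
  r <- regression(c(1, 2, 3), c(1, 2, 3))
  expect_equal(unlist(r), c(slope = 1, intercept = 0, r2 = 1))
  r2 <- regression(c(1, 2, 3), c(2, 4, 6))
  expect_equal(unlist(r2), c(slope = 2, intercept = 0, r2 = 1))

  set.seed(21)
  for (trial in 1:50) {
    x <- runif(sample(5:40, 1), 1, 100)
    y <- 0.8 * x + rnorm(length(x), 0, 5)
    got <- regression(x, y)
    fit <- lm(y ~ x)
    expect_equal(got$slope, unname(coef(fit)[2]), tolerance = 1e-12)
    expect_equal(got$intercept, unname(coef(fit)[1]), tolerance = 1e-12)
    expect_equal(got$r2, summary(fit)$r.squared, tolerance = 1e-12)
  }
  # slope of (ref, c * ref) equals c exactly
  x <- c(4, 7, 11, 13)
  for (cc in c(0.5, 1.15, 3))
    expect_equal(regression(x, cc * x)$slope, cc, tolerance = 1e-12)
  expect_error(regression(c(2, 2, 2), c(1, 2, 3)), "degenerate")
  expect_error(regression(1, 2), "length")
})

test_that("nrmse matches its definition and is scale-free", {
  expect_equal(nrmse(c(3, 8, 1), c(3, 8, 1)), 0)
  expect_equal(nrmse(c(0, 10), c(1, 9)), 0.1)
  set.seed(22)
  for (trial in 1:50) {
    x <- runif(12, 1, 50); y <- runif(12, 1, 50)
    expect_equal(nrmse(x, y),
                 sqrt(mean((y - x)^2)) / (max(x) - min(x)),
                 tolerance = 1e-12)
    expect_equal(nrmse(3.7 * x, 3.7 * y), nrmse(x, y), tolerance = 1e-12)
  }
  expect_error(nrmse(c(5, 5), c(1, 2)), "zero normalization range")
})

test_that("distance statistics use the population SD", {
  d <- distance_stats(c(3, 4), c(0, 0, 0), c(1, 2, 3))
  expect_equal(d$mean[d$category == "centroid"], 3.5)
  expect_equal(d$sd[d$category == "centroid"], 0.5)
  expect_equal(d$sd[d$category == "junction"], 0)
  set.seed(23)
  x <- runif(40)
  d2 <- suppressWarnings(distance_stats(x))
  expect_equal(d2$mean, mean(x), tolerance = 1e-12)
  expect_equal(d2$sd, sqrt(sum((x - mean(x))^2) / length(x)), tolerance = 1e-12)
  expect_warning(distance_stats(c(1, 2)), "junction")
})

test_that("count/size deltas and the accuracy formula are signed correctly", {
  g <- fix_wing()$geom
  expect_true(all(count_and_size_deltas(g, g) == 0))
  g2 <- g
  g2$n_cells <- g$n_cells - 2L
  g2$wing_area <- g$wing_area - 100
  d <- count_and_size_deltas(g, g2)
  expect_equal(unname(d["delta_n_cells"]), 2)
  expect_equal(unname(d["delta_wing_area"]), 100)

  expect_equal(accuracy_percent(200, 198), 1)
  expect_equal(accuracy_percent(57.3, 57.3), 0)
  expect_error(accuracy_percent(0, 1), "nonzero")
})

test_that("evaluating a wing against itself is a perfect-symmetry fixed point", {
  g <- fix_wing()$geom
  res <- evaluate_pair(g, g)
  expect_true(all(res$metrics$r2 == 1))
  expect_true(all(res$metrics$nrmse == 0))
  expect_true(all(res$metrics$slope == 1))
  expect_true(all(res$distances$mean < 1e-6))
  expect_true(all(res$deltas == 0))
  expect_lt(res$outline_mean_symmetric, 1e-6)
})

test_that("reference directions coincide for an unperturbed pair", {
  pr <- generate_pair(synth_config(seed = 12, n_cells = 20,
                                   height = 256, width = 384))
  g1 <- segment_all(binarize(pr$right))
  g2 <- segment_all(mirror_horizontal(binarize(pr$left)))
  res <- evaluate_pair(g1, g2)
  m1 <- res$metrics[res$metrics$direction == 1, -1]
  m2 <- res$metrics[res$metrics$direction == 2, -1]
  expect_equal(m1, m2, ignore_attr = TRUE, tolerance = 1e-9)
})
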