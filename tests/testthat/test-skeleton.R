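# Skeletonization operates on the vein (dark) phase, so fixtures build
# masks with TRUE = membrane and the structure of interest FALSE.

vein_binary <- function(veins) as_binary(!veins)

test_that("a thick bar thins to a 1-px centerline of similar extent", {
  veins <- matrix(FALSE, 20, 40)
  veins[8:12, 5:35] <- TRUE
  sk <- skeletonize(vein_binary(veins))$mask
  expect_equal(sum(rowSums(sk) > 0), 1)          # single row: 1 px thick
  expect_gte(sum(sk), 31 - 6)                    # end erosion <= half-width + 1
  # no 2x2 block anywhere
  blocks <- sk[-1, -1] & sk[-nrow(sk), -1] & sk[-1, -ncol(sk)] &
    sk[-nrow(sk), -ncol(sk)]
  expect_false(any(blocks))
})

test_that("thinning is idempotent on already-thin structures", {
  veins <- matrix(FALSE, 15, 15)
  veins[8, 2:14] <- TRUE
  sk1 <- skeletonize(vein_binary(veins))$mask
  expect_identical(sk1, veins)
  diagv <- matrix(FALSE, 15, 15)
  diagv[cbind(2:14, 2:14)] <- TRUE
  expect_identical(skeletonize(vein_binary(diagv))$mask, diagv)
})

test_that("thinning an annulus preserves its topology", {
  n <- 41; ctr <- 21
  idx <- expand.grid(r = 1:n, c = 1:n)
  d <- sqrt((idx$r - ctr)^2 + (idx$c - ctr)^2)
  veins <- matrix(d >= 8 & d <= 15, n, n)
  sk <- skeletonize(vein_binary(veins))$mask
  # oracle: independent BFS labeling; 8-connectivity for the skeleton
  # phase, dual 4-connectivity for its complement
  euler <- function(m) c(fg = count_components(m, 8),
                         bg = count_components(!m, 4))
  expect_equal(euler(sk), euler(veins))   # 1 component, hole kept (bg = 2)
  expect_equal(unname(euler(sk)["bg"]), 2)
  blocks <- sk[-1, -1] & sk[-n, -1] & sk[-1, -n] & sk[-n, -n]
  expect_false(any(blocks))
})

test_that("branch points are detected once per anatomical junction", {
  mk <- function() matrix(FALSE, 21, 21)
  sk_of <- function(veins) structure(list(mask = veins, dims = dim(veins)),
                                     class = "wa_skeleton")
  plus <- mk(); plus[11, 3:19] <- TRUE; plus[3:19, 11] <- TRUE
  j <- detect_junctions(sk_of(plus), prune = 0)
  expect_equal(nrow(j), 1)
  expect_equal(c(j$row, j$col), c(11, 11), tolerance = 1)

  line <- mk(); line[11, 3:19] <- TRUE
  expect_equal(nrow(detect_junctions(sk_of(line), prune = 0)), 0)

  yshape <- mk()
  yshape[11:19, 11] <- TRUE                       # stem down
  yshape[cbind(10:4, 10:4)] <- TRUE               # upper-left branch
  yshape[cbind(10:4, 12:18)] <- TRUE              # upper-right branch
  expect_equal(nrow(detect_junctions(sk_of(yshape), prune = 0)), 1)

  tshape <- mk(); tshape[11, 3:19] <- TRUE; tshape[12:19, 11] <- TRUE
  expect_equal(nrow(detect_junctions(sk_of(tshape), prune = 0)), 1)
})

test_that("junction detection is deterministic and pose-invariant", {
  fx <- fix_wing()
  b <- binarize(fx$raw)
  j1 <- detect_junctions(skeletonize(b))
  j2 <- detect_junctions(skeletonize(b))
  expect_identical(j1, j2)

  jm <- detect_junctions(skeletonize(mirror_horizontal(b)))
  expect_equal(nrow(jm), nrow(j1))

  rot <- b
  rot$mask <- t(b$mask)[rev(seq_len(ncol(b$mask))), , drop = FALSE]  # 90 deg
  jr <- detect_junctions(skeletonize(rot))
  expect_equal(nrow(jr), nrow(j1))
})

test_that("spur pruning removes short free-ended artifacts only", {
  veins <- matrix(FALSE, 21, 30)
  veins[11, 3:27] <- TRUE      # long line
  veins[8:10, 15] <- TRUE      # 3-px spur onto it
  sk <- structure(list(mask = veins, dims = dim(veins)), class = "wa_skeleton")
  expect_equal(nrow(detect_junctions(sk, prune = 0)), 1)  # spur fires a branch
  expect_equal(nrow(detect_junctions(sk, prune = 5)), 0)  # pruned away
})
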