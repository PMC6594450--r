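test_that("geodesic distance handles the degenerate limits exactly", {
  # constant image: the gradient integrand vanishes, every distance is zero
  const <- matrix(5, 6, 7)
  gm <- geodesic_distance(const, cbind(3L, 4L))
  expect_true(all(gm$distances == 0))

  # distance at a seed is zero regardless of the image
  img <- matrix(runif(30, min = 0, max = 3), 5, 6)
  gm <- geodesic_distance(img, cbind(2L, 5L))
  expect_identical(gm$distances[2, 5], 0)
  expect_true(all(gm$distances >= 0))

  # 1x4 strip (0, 0, 1, 1): the only path accumulates one unit step
  strip <- matrix(c(0, 0, 1, 1), 1, 4)
  gm <- geodesic_distance(strip, cbind(1L, 1L))
  expect_equal(gm$distances[1, 4], 1)
  expect_equal(gm$distances[1, 4],
               oracle_geodesic(strip, cbind(1L, 1L))[1, 4])
})

test_that("geodesic distance rejects empty and out-of-range seeds", {
  img <- matrix(runif(16), 4, 4)
  expect_error(geodesic_distance(img, matrix(integer(), 0, 2)), "no seeds")
  expect_error(geodesic_distance(img, cbind(5L, 1L)), "invalid scribble")
  expect_error(geodesic_distance(img, cbind(0L, 2L)), "invalid scribble")
})

test_that("raster-scan distances match Dijkstra on random 2D and 3D images", {
  set.seed(41)
  for (i in 1:12) {
    dims <- c(sample(5:12, 1), sample(5:12, 1))
    img <- array(runif(prod(dims)), dims)
    seeds <- cbind(sample(dims[1], 2, TRUE), sample(dims[2], 2, TRUE))
    gm <- geodesic_distance(img, seeds)
    expect_true(gm$converged)
    expect_lt(max(abs(gm$distances - oracle_geodesic(img, seeds))), 1e-6)
  }
  for (i in 1:5) {
    dims <- c(sample(4:7, 1), sample(4:7, 1), sample(4:7, 1))
    img <- array(runif(prod(dims)), dims)
    seeds <- cbind(sample(dims[1], 2, TRUE), sample(dims[2], 2, TRUE),
                   sample(dims[3], 2, TRUE))
    vol <- image_volume(array(img, c(dims, 1L)), ndim = 3L)
    gm <- geodesic_distance(vol, seeds)
    expect_lt(max(abs(gm$distances - oracle_geodesic(img, seeds))), 1e-6)
  }
})

test_that("distances are monotone in the seed set and linear in intensity", {
  set.seed(17)
  for (i in 1:10) {
    img <- matrix(runif(10 * 9), 10, 9)
    s1 <- cbind(sample(10, 1), sample(9, 1))
    extra <- cbind(sample(10, 1), sample(9, 1))
    d1 <- geodesic_distance(img, s1)$distances
    d2 <- geodesic_distance(img, rbind(s1, extra))$distances
    # a larger seed set can only shrink the min over seeds
    expect_true(all(d2 <= d1 + 1e-12))
    # scaling all intensities scales every path cost
    k <- runif(1, 0, 4)
    dk <- geodesic_distance(k * img, s1)$distances
    expect_equal(dk, k * d1, tolerance = 1e-10)
  }
})

test_that("fast mode runs a single pass pair", {
  img <- matrix(runif(64), 8, 8)
  gm <- geodesic_distance(img, cbind(1L, 1L), mode = "fast")
  expect_identical(gm$pairs, 1L)
})

test_that("encode_interactions builds the C_I + 3 stack in fixed order", {
  set.seed(3)
  img <- image_volume(matrix(runif(64), 8, 8))
  seg <- matrix(runif(64), 8, 8)
  scr <- scribble_set(foreground = cbind(2L, 2L), background = cbind(7L, 7L))
  stack <- encode_interactions(img, scr, seg, rng_seed = 9L)
  expect_identical(dim(stack), c(8L, 8L, 4L))
  expect_equal(stack[, , 1], img$data[, , 1])
  expect_equal(stack[, , 2], seg)
  # both interaction channels are computed and normalized to max 1
  expect_true(all(attr(stack, "channel_valid")))
  expect_equal(max(stack[, , 3]), 1)
  expect_equal(max(stack[, , 4]), 1)
  expect_identical(stack[2, 2, 3], 0)  # zero at the seed
  expect_identical(stack[7, 7, 4], 0)
})

test_that("empty scribble classes get seeded, reproducible random fill", {
  img <- image_volume(matrix(runif(64), 8, 8))
  seg <- matrix(0.5, 8, 8)
  none <- scribble_set()
  s1 <- encode_interactions(img, none, seg, rng_seed = 4L)
  s2 <- encode_interactions(img, none, seg, rng_seed = 4L)
  s3 <- encode_interactions(img, none, seg, rng_seed = 5L)
  expect_identical(s1, s2)
  expect_false(identical(s1[, , 3], s3[, , 3]))
  expect_identical(attr(s1, "channel_valid"),
                   c(foreground = FALSE, background = FALSE))
  expect_true(all(s1[, , 3] >= 0 & s1[, , 3] <= 1))

  # one-sided scribbles: computed foreground map, random-filled background
  fg_only <- scribble_set(foreground = cbind(4L, 4L))
  s4 <- encode_interactions(img, fg_only, seg, rng_seed = 4L)
  expect_identical(attr(s4, "channel_valid"),
                   c(foreground = TRUE, background = FALSE))
  ref <- geodesic_distance(img, cbind(4L, 4L))$distances
  expect_equal(s4[, , 3], ref / max(ref), tolerance = 1e-12)
})

test_that("encode_interactions rejects incongruent segmentations", {
  img <- image_volume(matrix(0, 8, 8))
  expect_error(
    encode_interactions(img, scribble_set(), matrix(0, 7, 8), rng_seed = 1L),
    "incompatible inputs")
})
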