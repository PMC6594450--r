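test_that("mis-segmented regions are the components of the disagreement", {
  truth <- matrix(0L, 20, 20)
  truth[6:15, 6:15] <- 1L
  # perfect agreement: nothing to report
  expect_length(find_misseg_regions(truth, truth), 0L)
  # everything missed: one under-segmented region of the full square
  regions <- find_misseg_regions(matrix(0L, 20, 20), truth)
  expect_length(regions, 1L)
  expect_identical(regions[[1]]$kind, "under")
  expect_identical(regions[[1]]$size, 100L)
  # spurious disjoint blob: one over-segmented region of 5 pixels
  auto <- truth
  auto[1, 1:5] <- 1L
  regions <- find_misseg_regions(auto, truth)
  expect_length(regions, 1L)
  expect_identical(regions[[1]]$kind, "over")
  expect_identical(regions[[1]]$size, 5L)
  expect_error(find_misseg_regions(matrix(0L, 3, 3), truth),
               "incompatible inputs")
})

test_that("click counts follow the size threshold and ceiling rule", {
  expect_identical(click_count(c(1, 29, 30, 100, 101, 250, 999)),
                   c(0L, 0L, 1L, 1L, 2L, 3L, 10L))
})

test_that("clicks are sampled inside their region with the right label", {
  truth <- matrix(0L, 30, 30)
  truth[4:20, 4:20] <- 1L  # 289 pixels -> 3 clicks when fully missed
  scr <- simulate_interactions(matrix(0L, 30, 30), truth, rng_seed = 5L)
  expect_identical(nrow(scr$foreground), 3L)
  expect_identical(nrow(scr$background), 0L)
  expect_true(all(truth[scr$foreground] == 1L))
  # determinism under the seed
  scr2 <- simulate_interactions(matrix(0L, 30, 30), truth, rng_seed = 5L)
  expect_identical(scr, scr2)
  # perfect segmentation: nothing simulated
  expect_identical(n_scribbles(simulate_interactions(truth, truth, 1L)), 0L)
})

test_that("total click count matches a brute-force recount over random degradations", {
  set.seed(61)
  for (rep in 1:8) {
    fx <- make_image(fixture_config(extent = 48L, rng_seed = 100L + rep))
    mode <- sample(c("erode", "dilate", "shift"), 1)
    auto <- degrade_segmentation(fx$truth, mode, magnitude = sample(1:3, 1),
                                 rng_seed = rep)
    if (sum(auto) == 0L) next
    scr <- simulate_interactions(auto, fx$truth, rng_seed = rep)
    regions <- find_misseg_regions(auto, fx$truth)
    expected <- sum(vapply(regions, function(r) click_count(r$size), integer(1)))
    expect_identical(n_scribbles(scr), as.integer(expected))
    # label correctness: fg clicks on missed foreground, bg on spurious
    if (nrow(scr$foreground)) {
      expect_true(all(fx$truth[scr$foreground] == 1L & auto[scr$foreground] == 0L))
    }
    if (nrow(scr$background)) {
      expect_true(all(fx$truth[scr$background] == 0L & auto[scr$background] == 1L))
    }
  }
})

test_that("within-region sampling is uniform (chi-square, scaled down)", {
  region <- structure(list(kind = "under",
                           pixels = which(matrix(TRUE, 10, 10), arr.ind = TRUE),
                           size = 100L),
                      class = "misseg_region")
  counts <- integer(100)
  for (rep in 1:2000) {
    cl <- clicks_for_region(region, rng_seed = rep)
    idx <- (cl$pixels[, 2] - 1L) * 10L + cl$pixels[, 1]
    counts[idx] <- counts[idx] + 1L
  }
  # 2000 single-click draws over 100 cells: chi-square GOF against uniform
  p <- stats::chisq.test(counts)$p.value
  expect_gt(p, 1e-4)
  expect_identical(cl$label, "foreground")
})

test_that("optional dilation grows clicks without leaving the region", {
  truth <- matrix(0L, 25, 25)
  truth[5:20, 5:20] <- 1L
  scr <- simulate_interactions(matrix(0L, 25, 25), truth, rng_seed = 2L,
                               dilate_radius = 1L)
  expect_gt(nrow(scr$foreground), 3L)
  expect_true(all(truth[scr$foreground] == 1L))
})
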