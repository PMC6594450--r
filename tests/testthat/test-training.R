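test_that("dataset normalization is exact, persistent, and guards degeneracy", {
  set.seed(2)
  imgs <- lapply(1:4, function(i) image_volume(matrix(runif(64, 0, 3), 8, 8)))
  norm <- normalize_dataset(imgs)
  all_vals <- unlist(lapply(norm$images, function(im) as.numeric(im$data)))
  expect_lt(abs(mean(all_vals)), 1e-6)
  expect_lt(abs(sd(all_vals) - 1), 1e-6)
  # re-applying the saved statistics reproduces the set bit-identically
  redo <- lapply(imgs, apply_normalization, stats = norm$stats)
  expect_identical(redo, norm$images)
  expect_error(normalize_dataset(list(image_volume(matrix(2, 8, 8)))),
               "degenerate data")
})

test_that("augmentation is seed-reproducible, identity-at-neutral, and mask-safe", {
  fx <- make_image(fixture_config(extent = 32L, rng_seed = 6L))
  a1 <- augment(fx$image, fx$truth, rng_seed = 13L)
  a2 <- augment(fx$image, fx$truth, rng_seed = 13L)
  expect_identical(a1, a2)
  expect_true(all(a1$mask %in% c(0L, 1L)))
  neutral <- augment(fx$image, fx$truth, rng_seed = 13L, flips = FALSE,
                     rotation = 0, zoom = c(1, 1))
  expect_equal(neutral$image$data, fx$image$data, tolerance = 1e-12)
  expect_identical(neutral$mask, fx$truth)
})

test_that("the learning-rate schedule halves every interval", {
  cfg <- train_config("pnet_pretrain", desk_scale = 1)
  expect_equal(learning_rate_at(cfg, 0), 1e-3)
  expect_equal(learning_rate_at(cfg, 4999), 1e-3)
  expect_equal(learning_rate_at(cfg, 5000), 5e-4)
  expect_equal(learning_rate_at(cfg, 10000), 2.5e-4)  # initial / 4
})

test_that("stage ordering is enforced", {
  data <- make_blob_set(2, 24L, 900)
  cfg_joint <- train_config("joint_pnet", desk_scale = 5000, channels = 2L)
  expect_error(train_stage(cfg_joint, data), "ordering violation")
  cfg_rnet <- train_config("rnet", desk_scale = 5000, channels = 2L)
  expect_error(train_stage(cfg_rnet, data), "ordering violation")
})

test_that("P-Net pre-training halves its loss on a separable task", {
  data <- make_blob_set(8, 24L, 300)
  cfg <- train_config("pnet_pretrain", desk_scale = 500, channels = 4L,
                      rng_seed = 2L, augment_enabled = FALSE)
  ck <- train_stage(cfg, data)
  tr <- ck$loss_trace
  expect_identical(nrow(tr), cfg$max_iter)
  expect_lt(mean(tail(tr$loss, 10)), 0.5 * tr$loss[1])
  expect_equal(tr$lr[1], 1e-3)
})

test_that("training is deterministic under a fixed seed on fixed data", {
  data <- make_blob_set(3, 24L, 410)
  cfg <- train_config("pnet_pretrain", max_iter = 15L, channels = 2L,
                      rng_seed = 5L)
  a <- train_stage(cfg, data)
  b <- train_stage(cfg, data)
  expect_identical(a$loss_trace, b$loss_trace)
  expect_identical(a$net$params, b$net$params)
})

test_that("the full stage chain runs and respects its data flow", {
  data <- make_blob_set(6, 24L, 570)
  pp <- train_full_pipeline(data, desk_scale = 1000, channels = 4L,
                            crf_iterations = 1L, rng_seed = 3L,
                            augment_enabled = FALSE)
  expect_identical(pp$stage1$stage, "joint_pnet")
  expect_identical(pp$stage2$stage, "rnet")
  # R-Net consumes C_I + 3 channels built from stage-1 outputs
  expect_identical(pp$stage2$net$config$in_channels, 4L)
  expect_lt(pp$pairwise$mse_holdout, 1e-2)
  # inference runs end to end
  seg <- segment_image(pp$stage1, data[[1]]$image)
  expect_identical(dim(seg$prob), c(24L, 24L))
  scr <- simulate_interactions(seg$labels, data[[1]]$truth, rng_seed = 1L)
  ref <- refine_image(pp$stage2, data[[1]]$image, seg$prob, scr, rng_seed = 1L)
  expect_identical(dim(ref$labels), c(24L, 24L))
  if (n_scribbles(scr) > 0L && nrow(scr$foreground)) {
    expect_true(all(ref$labels[scr$foreground] == 1L))
  }
})

test_that("checkpoints round-trip through disk with identical forwards", {
  data <- make_blob_set(3, 24L, 810)
  cfg <- train_config("pnet_pretrain", max_iter = 10L, channels = 2L,
                      rng_seed = 7L)
  ck <- train_stage(cfg, data)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(ck, path)
  ck2 <- load_checkpoint(path)
  x <- data[[1]]$image$data
  expect_identical(net_forward(ck2$net, x)$scores,
                   net_forward(ck$net, x)$scores)
  expect_identical(attr(ck2, "manifest")$config_hash,
                   scribbleseg:::config_hash(ck$config))
})

test_that("3D augmentation transforms in-plane and keeps masks binary", {
  fx <- make_image(fixture_config(ndim = 3L, extent = c(20L, 20L, 16L),
                                  rng_seed = 4L))
  a <- augment(fx$image, fx$truth, rng_seed = 3L)
  expect_identical(dim(a$mask), c(20L, 20L, 16L))
  expect_true(all(a$mask %in% c(0L, 1L)))
  expect_identical(spatial_extent(a$image), c(20L, 20L, 16L))
  b <- augment(fx$image, fx$truth, rng_seed = 3L)
  expect_identical(a, b)
})
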