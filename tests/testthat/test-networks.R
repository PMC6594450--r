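test_that("dilation schedule doubles per block from the base dilation", {
  expect_identical(dilation_schedule(network_config(channels = 4L)),
                   c(1L, 2L, 4L, 8L, 16L))
  expect_identical(dilation_schedule(network_config(d = 2L, channels = 4L)),
                   c(2L, 4L, 8L, 16L, 32L))
  expect_identical(dilation_schedule(network_config(channels = 4L))[1], 1L)
})

test_that("receptive fields follow the closed forms for all base dilations", {
  coef <- c(4, 12, 36, 84, 180)
  for (d in 1:4) {
    cfg <- network_config(d = d, channels = 4L)
    expect_equal(receptive_field(cfg, 1:5), coef * d + 1)
  }
  expect_equal(receptive_field(network_config(d = 2L, channels = 4L), 5), 361)
  expect_error(receptive_field(network_config(channels = 4L), 6), "invalid block")
})

test_that("dilated convolution matches direct evaluation", {
  set.seed(23)
  # q = 1 is ordinary convolution; delta kernel is the identity
  x <- matrix(rnorm(48), 6, 8)
  w <- matrix(rnorm(9), 3, 3)
  expect_equal(dilated_convolution(x, w, q = 1), oracle_conv2d(x, w, 1),
               tolerance = 1e-12)
  delta <- matrix(0, 3, 3); delta[2, 2] <- 1
  expect_equal(dilated_convolution(x, delta, q = 3), x, tolerance = 1e-14)
  # dilation 2 against the nested-summation oracle
  x7 <- matrix(rnorm(49), 7, 7)
  expect_equal(dilated_convolution(x7, w, q = 2), oracle_conv2d(x7, w, 2),
               tolerance = 1e-12)
  # 3D: a 1-voxel impulse with an identity-centre kernel is unchanged
  x3 <- array(rnorm(5 * 4 * 3), c(5, 4, 3, 1))
  w3 <- array(0, c(3, 3, 3, 1, 1)); w3[2, 2, 2, 1, 1] <- 1
  expect_equal(dilated_convolution(x3, w3, q = 1), x3[, , , 1],
               tolerance = 1e-14)
})

test_that("2D networks preserve resolution for even and odd extents", {
  cfg <- network_config(channels = 2L, in_channels = 1L, hidden_cls = 2L)
  net <- build_network(cfg, seed = 1L)
  for (ext in list(c(5L, 8L), c(12L, 12L), c(7L, 13L))) {
    x <- array(rnorm(prod(ext)), c(ext, 1L))
    sc <- net_forward(net, x)$scores
    expect_identical(dim(sc), c(ext, 2L))
  }
})

test_that("3D networks restore the input extent after downsample/upsample", {
  cfg <- network_config(ndim = 3L, channels = 4L, in_channels = 1L,
                        hidden_cls = 4L)
  net <- build_network(cfg, seed = 1L)
  for (ext in list(c(8L, 8L, 6L), c(9L, 7L, 5L))) {
    x <- array(rnorm(prod(ext)), c(ext, 1L))
    sc <- net_forward(net, x)$scores
    expect_identical(dim(sc), c(ext, 2L))
  }
})

test_that("P-Net and R-Net differ only in the first-layer input channels", {
  pnet <- build_network(network_config(channels = 4L, in_channels = 1L),
                        seed = 1L)
  rnet <- build_network(network_config(channels = 4L, in_channels = 4L),
                        seed = 1L)
  shape <- function(net) rapply(net$params, dim, how = "list")
  sp <- shape(pnet); sr <- shape(rnet)
  expect_identical(sp$blocks[[1]][[1]]$w[1:2], sr$blocks[[1]][[1]]$w[1:2])
  expect_identical(sp$blocks[[1]][[1]]$w[3] + 3L, sr$blocks[[1]][[1]]$w[3])
  sp$blocks[[1]][[1]] <- NULL; sr$blocks[[1]][[1]] <- NULL
  expect_identical(sp, sr)
})

test_that("the 2D multiscale concatenation carries 5C channels", {
  cfg <- network_config(channels = 3L, in_channels = 1L, hidden_cls = 2L)
  net <- build_network(cfg, seed = 2L)
  x <- array(rnorm(100), c(10, 10, 1))
  fw <- net_forward(net, x, cache = TRUE)
  expect_identical(dim(fw$cache$concat)[3], 5L * 3L)
  expect_identical(dim(net$params$cls1$w)[3], 15L)
})

test_that("the executable receptive field is bounded by the analytic R5", {
  cfg <- network_config(channels = 2L, in_channels = 1L, hidden_cls = 2L)
  net <- build_network(cfg, seed = 5L)
  R5 <- receptive_field(cfg, 5)  # 181
  n <- R5 + 10L
  x <- array(0, c(n, n, 1L))
  fw <- net_forward(net, x, cache = TRUE)
  g <- array(0, dim(fw$scores))
  ctr <- (n + 1L) %/% 2L
  g[ctr, ctr, 1L] <- 1
  gx <- net_backward(net, fw$cache, g)$gx
  nz <- which(abs(gx[, , 1]) > 0, arr.ind = TRUE)
  expect_gt(nrow(nz), 0)
  half <- (R5 - 1) / 2
  expect_true(all(abs(nz[, 1] - ctr) <= half))
  expect_true(all(abs(nz[, 2] - ctr) <= half))
})

test_that("network gradients agree with finite differences", {
  set.seed(19)
  cfg <- network_config(channels = 3L, in_channels = 2L, hidden_cls = 3L)
  net <- build_network(cfg, seed = 2L)
  x <- array(rnorm(9 * 8 * 2), c(9, 8, 2))
  y <- sample(0:1, 72, TRUE)
  lossf <- function(net) {
    sc <- matrix(net_forward(net, x)$scores, 72, 2)
    q <- exp(sc - apply(sc, 1, max)); q <- q / rowSums(q)
    -mean(log(q[cbind(1:72, y + 1)]))
  }
  fw <- net_forward(net, x, cache = TRUE)
  sc <- matrix(fw$scores, 72, 2)
  q <- exp(sc - apply(sc, 1, max)); q <- q / rowSums(q)
  gsc <- q; gsc[cbind(1:72, y + 1)] <- gsc[cbind(1:72, y + 1)] - 1
  bw <- net_backward(net, fw$cache, array(gsc / 72, dim(fw$scores)))
  eps <- 1e-6
  probes <- list(
    list(\(n, e) { n$params$blocks[[2]][[2]]$w[7] <- n$params$blocks[[2]][[2]]$w[7] + e; n },
         \(g) g$blocks[[2]][[2]]$w[7]),
    list(\(n, e) { n$params$blocks[[5]][[1]]$b[1] <- n$params$blocks[[5]][[1]]$b[1] + e; n },
         \(g) g$blocks[[5]][[1]]$b[1]),
    list(\(n, e) { n$params$cls1$w[4] <- n$params$cls1$w[4] + e; n },
         \(g) g$cls1$w[4]),
    list(\(n, e) { n$params$cls2$w[2] <- n$params$cls2$w[2] + e; n },
         \(g) g$cls2$w[2]))
  for (p in probes) {
    num <- (lossf(p[[1]](net, eps)) - lossf(p[[1]](net, -eps))) / (2 * eps)
    expect_lt(abs(num - p[[2]](bw$grads)) / max(abs(num), 1e-8), 1e-3)
  }
})

test_that("network specs serialize to YAML and back", {
  net <- build_network(network_config(channels = 4L, in_channels = 2L), 1L)
  path <- tempfile(fileext = ".yaml")
  write_network_spec(net, path)
  spec <- yaml::read_yaml(path)
  expect_identical(spec$in_channels, 2L)
  expect_length(spec$blocks, 13L)
  expect_identical(spec$blocks[[13]]$dilation, 16L)
  expect_identical(spec$classifier[[1]]$kernel, 1L)
})
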