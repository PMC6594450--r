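test_that("the contrast-sensitive target evaluates per its definition", {
  expect_equal(pairwise_target(0, 1), 0.5)
  expect_equal(pairwise_target(c(0, 0), 2, sigma = 0.1, omega = 1), 0.5)
  # strictly decreasing in the feature difference at fixed distance
  v <- pairwise_target(matrix(seq(0, 1, by = 0.1)), d = 1)
  expect_true(all(diff(v) < 0))
  # omega / d scaling: doubling d halves the value
  expect_equal(pairwise_target(0.3, 2), pairwise_target(0.3, 1) / 2)
  expect_error(pairwise_target(0, 0), "invalid distance")
  expect_error(pairwise_target(0, -1), "invalid distance")
})

test_that("pairwise messages vanish for a zero net and match a 2-pixel oracle", {
  cfg <- crf_config(patch = c(3, 3), feature_dim = 1L)
  net0 <- pairwise_net(1L, seed = 1L)
  net0$params <- lapply(net0$params, function(p) p * 0)
  Q <- matrix(runif(8), 4, 2); Q <- Q / rowSums(Q)
  feats <- array(runif(4), c(2, 2, 1))
  mu <- compatibility_init(2)
  phi <- pairwise_message(Q, feats, net0, mu, cfg)
  expect_true(all(phi == 0))

  # 1x2 image: hand evaluation over the single ordered pair in each direction
  net <- pairwise_net(1L, seed = 7L)
  f <- array(c(0.2, 0.9), c(1, 2, 1))
  Q2 <- matrix(c(0.3, 0.8, 0.7, 0.2), 2, 2)
  mu2 <- matrix(c(0.1, 1.2, 0.9, -0.3), 2, 2)
  phi2 <- pairwise_message(Q2, f, net, mu2, crf_config(patch = c(3, 3)))
  f12 <- pairwise_net_forward(net, matrix(c(0.2 - 0.9, 1), 1))
  f21 <- pairwise_net_forward(net, matrix(c(0.9 - 0.2, 1), 1))
  for (l in 1:2) {
    expect_equal(phi2[1, l], sum(mu2[l, ] * f12 * Q2[2, ]), tolerance = 1e-12)
    expect_equal(phi2[2, l], sum(mu2[l, ] * f21 * Q2[1, ]), tolerance = 1e-12)
  }
})

test_that("uniform Q with symmetric mu gives label-constant messages inside a constant image", {
  cfg <- crf_config(patch = c(3, 3), feature_dim = 1L)
  net <- pairwise_net(1L, seed = 2L)
  feats <- array(1, c(5, 5, 1))
  Q <- matrix(0.5, 25, 2)
  mu <- matrix(c(0.2, 0.7, 0.7, 0.2), 2, 2)
  phi <- pairwise_message(Q, feats, net, mu, cfg)
  expect_equal(phi[, 1], phi[, 2], tolerance = 1e-12)
})

test_that("mean-field iterations match the scalar oracle on small instances", {
  set.seed(31)
  for (rep in 1:6) {
    dims <- c(sample(2:4, 1), sample(2:4, 1))
    T_it <- sample(1:3, 1)
    cfg <- crf_config(patch = c(3, 3), iterations = T_it, feature_dim = 1L)
    net <- pairwise_net(1L, seed = rep)
    mu <- compatibility_init(2) + matrix(rnorm(4, sd = 0.2), 2, 2)
    S <- array(rnorm(prod(dims) * 2), c(dims, 2))
    feats <- array(runif(prod(dims)), c(dims, 1))
    res <- crf_forward(S, feats, net, mu, cfg)
    ref <- oracle_mean_field(S, feats, net, mu, cfg, T_it)
    expect_lt(max(abs(res$Q - ref)), 1e-6)
    # with constraints
    scr <- scribble_set(foreground = cbind(1L, 1L),
                        background = cbind(dims[1], dims[2]))
    res2 <- crf_forward(S, feats, net, mu, cfg, scribbles = scr)
    ref2 <- oracle_mean_field(S, feats, net, mu, cfg, T_it,
                              cons_idx = c(1L, prod(dims)),
                              cons_lab = c(1L, 0L))
    expect_lt(max(abs(res2$Q - ref2)), 1e-6)
    expect_identical(res2$Q[1, 2], 1)
    expect_identical(res2$Q[prod(dims), 1], 1)
  }
})

test_that("Q stays a distribution and constraints are exact after every iteration", {
  set.seed(12)
  cfg <- crf_config(iterations = 1L, feature_dim = 1L)
  net <- pairwise_net(1L, seed = 4L)
  mu <- compatibility_init(2)
  S <- array(rnorm(7 * 6 * 2, sd = 2), c(7, 6, 2))
  feats <- array(runif(42), c(7, 6, 1))
  scr <- scribble_set(foreground = rbind(c(2L, 2L), c(3L, 3L)),
                      background = cbind(6L, 5L))
  state <- mean_field_state(S, feats, net, mu, cfg, scribbles = scr)
  for (t in 1:3) {
    state <- mean_field_iterate(state, iterations = 1L)
    expect_true(all(abs(rowSums(state$Q) - 1) < 1e-6))
    expect_true(all(state$Q >= 0))
    expect_identical(state$Q[cbind(c(9L, 17L), 2L)], c(1, 1))
    expect_identical(state$Q[34L, 1L], 1)
  }
})

test_that("conflicting scribbles are rejected", {
  expect_error(scribble_set(foreground = cbind(2L, 2L),
                            background = cbind(2L, 2L)),
               "inconsistent constraints")
})

test_that("a zero pairwise net recovers the unary-only distribution exactly", {
  cfg <- crf_config(iterations = 3L, feature_dim = 1L)
  net0 <- pairwise_net(1L, seed = 1L)
  net0$params <- lapply(net0$params, function(p) p * 0)
  S <- array(rnorm(5 * 5 * 2), c(5, 5, 2))
  feats <- array(runif(25), c(5, 5, 1))
  res <- crf_forward(S, feats, net0, compatibility_init(2), cfg)
  Sm <- matrix(S, 25, 2)
  e <- exp(Sm - apply(Sm, 1, max))
  expect_equal(res$Q, e / rowSums(e), tolerance = 1e-12)
})

test_that("strong unaries dominate a weak pairwise term", {
  cfg <- crf_config(iterations = 3L, feature_dim = 1L)
  net <- pairwise_net(1L, seed = 3L)
  net$params <- lapply(net$params, function(p) p * 0.01)
  set.seed(8)
  S <- array(0, c(8, 8, 2))
  S[, , 2] <- sample(c(-10, 10), 64, TRUE)  # decisive per-pixel preference
  feats <- array(runif(64), c(8, 8, 1))
  out <- crf_refine(S, image_volume(feats, ndim = 2L), NULL, cfg, net,
                    compatibility_init(2))
  unary_arg <- apply(matrix(S, 64, 2), 1, which.max) - 1L
  expect_identical(as.integer(out$labels), unary_arg)
})

test_that("a scribble contradicting the unary wins at that pixel", {
  cfg <- crf_config(iterations = 2L, feature_dim = 1L)
  net <- pairwise_net(1L, seed = 3L)
  S <- array(0, c(4, 4, 2))
  S[, , 1] <- 5  # unary strongly prefers background everywhere
  feats <- array(0.5, c(4, 4, 1))
  scr <- scribble_set(foreground = cbind(2L, 3L))
  out <- crf_refine(S, image_volume(feats, ndim = 2L), scr, cfg, net,
                    compatibility_init(2))
  expect_identical(out$labels[2, 3], 1L)
  expect_identical(out$prob[2, 3, 2], 1)
  expect_true(all(out$labels[-10] == 0L))
})

test_that("CRF smoothing repairs salt-and-pepper unary corruption on a disk", {
  set.seed(44)
  dims <- c(16L, 16L)
  co <- as.matrix(expand.grid(1:16, 1:16))
  disk <- matrix(as.integer((co[, 1] - 8.5)^2 + (co[, 2] - 8.5)^2 <= 25), 16, 16)
  feats <- array(0.2 + 0.6 * disk, c(dims, 1))
  S <- array(0, c(dims, 2))
  S[, , 2] <- 4 * (2 * disk - 1)
  flips <- sample(256, 25)
  Sm <- matrix(S[, , 2], 256)
  Sm[flips] <- -Sm[flips]
  S[, , 2] <- Sm
  unary_err <- sum((matrix(S[, , 2], 256) > 0) != as.logical(disk))
  # pairwise potential fixed at its contrast-sensitive initialization
  fit <- pretrain_pairwise_net(1L, n_samples = 5000L, rng_seed = 2L)
  cfg <- crf_config(iterations = 5L, feature_dim = 1L)
  out <- crf_refine(S, image_volume(feats, ndim = 2L), NULL, cfg, fit$net,
                    compatibility_init(2))
  crf_err <- sum((out$labels == 1L) != (disk == 1L))
  expect_lt(crf_err, unary_err)
})

test_that("gradients through two unrolled iterations match finite differences", {
  set.seed(27)
  cfg <- crf_config(patch = c(3, 3), iterations = 2L, feature_dim = 1L)
  net <- pairwise_net(1L, seed = 5L)
  mu <- compatibility_init(2) + matrix(rnorm(4, sd = 0.1), 2, 2)
  S <- array(rnorm(4 * 4 * 2), c(4, 4, 2))
  feats <- array(runif(16), c(4, 4, 1))
  y <- sample(0:1, 16, TRUE)
  lossf <- function(net, mu, S) {
    r <- crf_forward(S, feats, net, mu, cfg)
    -mean(log(pmax(r$Q[cbind(1:16, y + 1)], 1e-12)))
  }
  r <- crf_forward(S, feats, net, mu, cfg, cache = TRUE)
  n <- 16
  gQ <- matrix(0, n, 2)
  idx <- cbind(1:n, y + 1L)
  gQ[idx] <- -1 / pmax(r$Q[idx], 1e-8) / n
  gb <- crf_backward(r$cache, gQ)
  eps <- 1e-6
  for (ij in list(c(1, 1), c(1, 2), c(2, 1), c(2, 2))) {
    mp <- mu; mp[ij[1], ij[2]] <- mp[ij[1], ij[2]] + eps
    mm <- mu; mm[ij[1], ij[2]] <- mm[ij[1], ij[2]] - eps
    num <- (lossf(net, mp, S) - lossf(net, mm, S)) / (2 * eps)
    expect_lt(abs(num - gb$gmu[ij[1], ij[2]]) / max(abs(num), 1e-8), 1e-3)
  }
  for (nm in c("W1", "W2", "W3", "b1", "b3")) {
    for (k in sample(length(net$params[[nm]]), min(2, length(net$params[[nm]])))) {
      np <- net; np$params[[nm]][k] <- np$params[[nm]][k] + eps
      nn <- net; nn$params[[nm]][k] <- nn$params[[nm]][k] - eps
      num <- (lossf(np, mu, S) - lossf(nn, mu, S)) / (2 * eps)
      expect_lt(abs(num - gb$gnet[[nm]][k]) / max(abs(num), 1e-8), 1e-3)
    }
  }
  for (k in sample(32, 3)) {
    Sp <- S; Sp[k] <- Sp[k] + eps
    Sm2 <- S; Sm2[k] <- Sm2[k] - eps
    num <- (lossf(net, mu, Sp) - lossf(net, mu, Sm2)) / (2 * eps)
    expect_lt(abs(num - gb$gscores[k]) / max(abs(num), 1e-8), 1e-3)
  }
})

test_that("pre-training reproduces its sample set under a fixed seed and tracks the target", {
  f1 <- pretrain_pairwise_net(1L, n_samples = 2000L, rng_seed = 11L,
                              epochs = 5L)
  f2 <- pretrain_pairwise_net(1L, n_samples = 2000L, rng_seed = 11L,
                              epochs = 5L)
  expect_identical(f1$net$params, f2$net$params)
  expect_identical(f1$mse_holdout, f2$mse_holdout)

  # desk-scale run reaches the stated accuracy band on held-out samples
  fit <- pretrain_pairwise_net(1L, n_samples = 10000L, rng_seed = 1L)
  expect_lt(fit$mse_holdout, 1e-2)
  # and its outputs track the target on a deterministic (ftilde, d) grid
  grid <- as.matrix(expand.grid(seq(-4, 4, length.out = 41),
                                seq(1, 8, length.out = 15)))
  pred <- pairwise_net_forward(fit$net, grid)
  ref <- pairwise_target(grid[, 1, drop = FALSE], grid[, 2])
  expect_lt(mean((pred - ref)^2), 1e-2)
})

test_that("the 3D CRF with its 5x5x3 patch matches the scalar oracle", {
  set.seed(91)
  dims <- c(3L, 3L, 3L)
  cfg <- crf_config(ndim = 3L, iterations = 2L, feature_dim = 1L)
  expect_identical(cfg$patch, c(5L, 5L, 3L))
  net <- pairwise_net(1L, seed = 9L)
  mu <- compatibility_init(2)
  S <- array(rnorm(prod(dims) * 2), c(dims, 2))
  feats <- array(runif(prod(dims)), c(dims, 1))
  res <- crf_forward(S, feats, net, mu, cfg)
  ref <- oracle_mean_field(S, feats, net, mu, cfg, 2L)
  expect_lt(max(abs(res$Q - ref)), 1e-6)
})
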