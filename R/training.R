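#' Normalize a training set
#'
#' Computes global per-channel mean and standard deviation over the whole
#' training set and standardizes every image with them. The statistics are
#' returned so they can be persisted and re-applied verbatim at inference.
#'
#' @param images List of `image_volume`s with a common channel count.
#' @return List with `images` (normalized) and `stats`
#'   (`list(mean, sd)` per channel).
#' @export
normalize_dataset <- function(images) {
  stopifnot(length(images) > 0L)
  images <- lapply(images, as_image_volume)
  nc <- n_channels(images[[1L]])
  ch_vals <- lapply(seq_len(nc), function(c) {
    unlist(lapply(images, function(im) as.numeric(channel_data(im, c))))
  })
  mu <- vapply(ch_vals, mean, numeric(1))
  sdv <- vapply(ch_vals, sd, numeric(1))
  if (any(sdv < 1e-12)) stop("degenerate data: zero-variance channel")
  stats <- list(mean = mu, sd = sdv)
  list(images = lapply(images, apply_normalization, stats = stats),
       stats = stats)
}

#' Apply saved normalization statistics to an image
#' @param image An `image_volume`.
#' @param stats Statistics from [normalize_dataset()].
#' @return The normalized `image_volume`.
#' @export
apply_normalization <- function(image, stats) {
  image <- as_image_volume(image)
  nc <- n_channels(image)
  flat <- prod(spatial_extent(image))
  for (c in seq_len(nc)) {
    idx <- (c - 1L) * flat + seq_len(flat)
    image$data[idx] <- (image$data[idx] - stats$mean[c]) / stats$sd[c]
  }
  image
}

#' Random geometric augmentation of an image/mask pair
#'
#' Applies one identical random transform to both: horizontal/vertical flips
#' with probability 1/2 each, rotation with angle uniform on
#' `[-rotation, rotation]`, and zoom with factor uniform on `zoom`. The
#' image is resampled bilinearly, the mask with nearest neighbour so it
#' stays binary. In 3D the rotation and zoom act in-plane (axes 1-2),
#' slice by slice.
#'
#' @param image An `image_volume`.
#' @param mask Integer array congruent with the image.
#' @param rng_seed Integer seed; fixed seed gives identical output.
#' @param flips Enable random flips.
#' @param rotation Max rotation angle in radians (default pi/8).
#' @param zoom Zoom factor range (default `c(0.8, 1.25)`).
#' @return List with transformed `image` and `mask`.
#' @export
augment <- function(image, mask, rng_seed, flips = TRUE, rotation = pi / 8,
                    zoom = c(0.8, 1.25)) {
  image <- as_image_volume(image)
  ext <- spatial_extent(image)
  if (!identical(as.integer(dim(mask)), as.integer(ext))) {
    stop("incompatible inputs: image and mask extents differ")
  }
  prm <- with_seed(rng_seed, list(
    flip = if (flips) runif(2L) < 0.5 else c(FALSE, FALSE),
    theta = runif(1L, -rotation, rotation),
    z = runif(1L, zoom[1L], zoom[2L])
  ))
  # output -> input affine about the image centre (0-based coordinates)
  ctr <- (ext[1:2] - 1) / 2
  Rm <- matrix(c(cos(prm$theta), sin(prm$theta),
                 -sin(prm$theta), cos(prm$theta)), 2L, 2L)
  Fm <- diag(ifelse(prm$flip, -1, 1))
  M <- (t(Rm) %*% Fm) / prm$z
  v <- ctr - M %*% ctr
  warp_all <- function(arr, interp) {
    if (image$ndim == 2L) {
      cpp_warp2d(arr, M, as.numeric(v), interp, 0)
    } else {
      out <- arr
      for (z in seq_len(ext[3L])) {
        sl <- arr[, , z, , drop = FALSE]
        dim(sl) <- dim(arr)[c(1L, 2L, 4L)]
        out[, , z, ] <- cpp_warp2d(sl, M, as.numeric(v), interp, 0)
      }
      out
    }
  }
  img_out <- image
  img_out$data <- warp_all(image$data, 1L)
  mask_arr <- array(as.numeric(mask), c(ext, 1L))
  mask_out <- warp_all(mask_arr, 0L)
  dim(mask_out) <- ext
  list(image = img_out, mask = array(as.integer(mask_out), ext))
}

#' Training configuration
#'
#' One stage of the three-step protocol. Full-scale settings follow the
#' published recipe (minibatch 1, momentum 0.99, weight decay 5e-4, learning
#' rate halved every 5000 iterations, 100k pre-training / 50k joint
#' iterations); `desk_scale` divides the maximum iteration counts for
#' laptop-sized runs (the halving interval is untouched).
#'
#' @param stage `"pnet_pretrain"`, `"pairwise_pretrain"`, `"joint_pnet"`, or
#'   `"rnet"`.
#' @param ndim Spatial dimensionality.
#' @param desk_scale Divisor applied to iteration counts (1 = full scale;
#'   default 200).
#' @param lr Initial learning rate; stage-specific default.
#' @param momentum SGD momentum (default 0.99).
#' @param weight_decay L2 weight decay (default 5e-4).
#' @param max_iter Maximum iterations; stage default divided by
#'   `desk_scale`.
#' @param lr_halve_every Halving interval (default 5000 / `desk_scale`).
#' @param minibatch Minibatch size (default 1).
#' @param augment_flips,augment_rotation,augment_zoom Augmentation switches.
#' @param augment_enabled Master augmentation switch.
#' @param crf_iterations Mean-field iterations unrolled during joint
#'   training.
#' @param channels Block width C of the networks trained in this stage.
#' @param rng_seed Integer seed.
#' @return A `train_config` object.
#' @export
train_config <- function(stage = c("pnet_pretrain", "pairwise_pretrain",
                                   "joint_pnet", "rnet"),
                         ndim = 2L, desk_scale = 200, lr = NULL,
                         momentum = 0.99, weight_decay = 5e-4,
                         max_iter = NULL, lr_halve_every = NULL,
                         minibatch = 1L, augment_flips = TRUE,
                         augment_rotation = pi / 8,
                         augment_zoom = c(0.8, 1.25),
                         augment_enabled = TRUE, crf_iterations = 5L,
                         channels = NULL, rng_seed = 1L) {
  stage <- match.arg(stage)
  stopifnot(desk_scale >= 1, momentum >= 0, momentum < 1, weight_decay >= 0)
  full_iter <- switch(stage, pnet_pretrain = 100000L,
                      pairwise_pretrain = 100000L, joint_pnet = 50000L,
                      rnet = 100000L)
  if (is.null(max_iter)) max_iter <- max(1L, as.integer(ceiling(full_iter / desk_scale)))
  # the halving interval stays at its published value: desk_scale shortens
  # the run, it does not accelerate the schedule (a desk run then trains at
  # an effectively constant rate, like the first segment of the full run)
  if (is.null(lr_halve_every)) lr_halve_every <- 5000L
  if (is.null(lr)) {
    # published initial rates: 1e-3 pre-training, 1e-6 joint fine-tuning.
    # At desk scale the joint stages keep a usable rate (1e-4) because 1e-6
    # over a few hundred iterations moves nothing.
    lr <- switch(stage,
                 pnet_pretrain = 1e-3,
                 pairwise_pretrain = 0.02,
                 joint_pnet = if (desk_scale > 1) 1e-4 else 1e-6,
                 rnet = 1e-3)
  }
  stopifnot(lr > 0, max_iter >= 1L)
  if (is.null(channels)) channels <- if (ndim == 2L) 64L else 16L
  structure(list(stage = stage, ndim = as.integer(ndim),
                 desk_scale = desk_scale, lr = lr, momentum = momentum,
                 weight_decay = weight_decay, max_iter = as.integer(max_iter),
                 lr_halve_every = as.integer(lr_halve_every),
                 minibatch = as.integer(minibatch),
                 augment = list(enabled = isTRUE(augment_enabled),
                                flips = isTRUE(augment_flips),
                                rotation = augment_rotation,
                                zoom = augment_zoom),
                 crf_iterations = as.integer(crf_iterations),
                 channels = as.integer(channels),
                 rng_seed = as.integer(rng_seed)),
            class = "train_config")
}

#' Learning rate at a given iteration
#'
#' Step schedule halved every `lr_halve_every` iterations, with the solver's
#' 0-based step convention: `lr(i) = lr0 * 0.5^floor(i / interval)`, so the
#' rate at iteration 10000 under the default interval is a quarter of the
#' initial rate.
#' @param config A `train_config`.
#' @param iteration Iteration number.
#' @return The learning rate.
#' @export
learning_rate_at <- function(config, iteration) {
  config$lr * 0.5^(iteration %/% config$lr_halve_every)
}

# Recursive helpers over nested parameter lists -------------------------------

params_map2 <- function(a, b, f) {
  if (is.list(a)) {
    out <- mapply(params_map2, a, b, MoreArgs = list(f = f), SIMPLIFY = FALSE)
    names(out) <- names(a)
    out
  } else {
    f(a, b)
  }
}

params_scale <- function(a, s) {
  if (is.list(a)) lapply(a, params_scale, s = s) else a * s
}

sgd_step <- function(params, vel, grads, lr, momentum, weight_decay) {
  vel <- params_map2(vel, params_map2(grads, params, function(g, p) {
    g + weight_decay * p
  }), function(v, g) momentum * v - lr * g)
  list(params = params_map2(params, vel, `+`), vel = vel)
}

softmax_ce <- function(scores_mat, y) {
  # y: 0-based labels per pixel; returns loss and dscores (mean over pixels)
  Q <- row_softmax(scores_mat)
  n <- nrow(Q)
  idx <- cbind(seq_len(n), y + 1L)
  loss <- -mean(log(pmax(Q[idx], 1e-12)))
  G <- Q
  G[idx] <- G[idx] - 1
  list(loss = loss, g = G / n)
}

q_ce <- function(Q, y) {
  n <- nrow(Q)
  idx <- cbind(seq_len(n), y + 1L)
  loss <- -mean(log(pmax(Q[idx], 1e-12)))
  G <- matrix(0, n, ncol(Q))
  G[idx] <- -1 / pmax(Q[idx], 1e-8) / n
  list(loss = loss, g = G)
}

draw_sample <- function(data, it) {
  data[[(it - 1L) %% length(data) + 1L]]
}

maybe_augment <- function(sample, config, it) {
  if (!config$augment$enabled) return(sample)
  aug <- augment(sample$image, sample$truth,
                 rng_seed = config$rng_seed + 7919L * it,
                 flips = config$augment$flips,
                 rotation = config$augment$rotation,
                 zoom = config$augment$zoom)
  list(image = aug$image, truth = aug$mask)
}

#' Run one training stage
#'
#' Implements the three-step protocol. `"pnet_pretrain"` trains P-Net alone
#' with per-pixel cross-entropy on its softmax scores. `"pairwise_pretrain"`
#' fits the Pairwise-Net to the contrast-sensitive target.
#' `"joint_pnet"` unrolls the mean-field CRF on top of the pre-trained P-Net
#' and trains network, compatibility matrix and Pairwise-Net end to end with
#' cross-entropy on the CRF output. `"rnet"` freezes the stage-1 model,
#' simulates user interactions on its training-set segmentations, builds the
#' geodesic input stacks, and trains R-Net (first alone, then jointly with
#' CRF-Net(fu) under the scribble hard constraints).
#'
#' @param config A `train_config`.
#' @param data List of samples, each `list(image = image_volume, truth =
#'   binary mask)`, un-normalized.
#' @param prev Checkpoint of the prerequisite stage: `"joint_pnet"` needs
#'   the `"pnet_pretrain"` checkpoint plus `pairwise` (a
#'   `"pairwise_pretrain"` result); `"rnet"` needs the `"joint_pnet"`
#'   checkpoint.
#' @param pairwise Pre-trained Pairwise-Net checkpoint where required.
#' @return A checkpoint: list with `stage`, `config`, stage outputs (`net`,
#'   `mu`, `pwnet`, `crf`, `stats` as applicable), and `loss_trace`
#'   (data frame iteration/lr/loss).
#' @export
train_stage <- function(config, data, prev = NULL, pairwise = NULL) {
  stopifnot(inherits(config, "train_config"))
  stage <- config$stage
  if (stage == "pairwise_pretrain") {
    n_samp <- if (config$desk_scale > 1) 10000L else 100000L
    fit <- pretrain_pairwise_net(feature_dim = 1L, n_samples = n_samp,
                                 rng_seed = config$rng_seed)
    return(structure(list(stage = stage, config = config, pwnet = fit$net,
                          mse_holdout = fit$mse_holdout,
                          loss_trace = data.frame(
                            iteration = seq_along(fit$loss_trace),
                            lr = NA_real_, loss = fit$loss_trace)),
                     class = "scribbleseg_checkpoint"))
  }
  stopifnot(length(data) > 0L)
  if (stage == "pnet_pretrain") {
    norm <- normalize_dataset(lapply(data, `[[`, "image"))
    samples <- mapply(function(im, s) list(image = im, truth = s$truth),
                      norm$images, data, SIMPLIFY = FALSE)
    nc <- n_channels(samples[[1L]]$image)
    net <- build_network(network_config(ndim = config$ndim,
                                        channels = config$channels,
                                        in_channels = nc),
                         seed = config$rng_seed)
    vel <- params_scale(net$params, 0)
    trace <- data.frame(iteration = integer(), lr = numeric(), loss = numeric())
    for (it in seq_len(config$max_iter)) {
      smp <- maybe_augment(draw_sample(samples, it), config, it)
      fw <- net_forward(net, smp$image$data, cache = TRUE)
      L <- net$config$num_labels
      sc <- matrix(fw$scores, length(smp$truth), L)
      ce <- softmax_ce(sc, as.integer(smp$truth))
      bw <- net_backward(net, fw$cache, array(ce$g, dim(fw$scores)))
      lr <- learning_rate_at(config, it)
      st <- sgd_step(net$params, vel, bw$grads, lr, config$momentum,
                     config$weight_decay)
      net$params <- st$params
      vel <- st$vel
      trace[nrow(trace) + 1L, ] <- list(it, lr, ce$loss)
    }
    return(structure(list(stage = stage, config = config, net = net,
                          stats = norm$stats, loss_trace = trace),
                     class = "scribbleseg_checkpoint"))
  }
  if (stage == "joint_pnet") {
    if (is.null(prev) || prev$stage != "pnet_pretrain") {
      stop("ordering violation: joint_pnet requires the pnet_pretrain checkpoint")
    }
    if (is.null(pairwise)) {
      stop("ordering violation: joint_pnet requires the pre-trained Pairwise-Net")
    }
    net <- prev$net
    stats <- prev$stats
    pw <- if (inherits(pairwise, "pairwise_net")) pairwise else pairwise$pwnet
    mu <- compatibility_init(net$config$num_labels)
    crf_cfg <- crf_config(ndim = config$ndim,
                          num_labels = net$config$num_labels,
                          iterations = config$crf_iterations,
                          feature_dim = n_channels(data[[1L]]$image))
    samples <- lapply(data, function(s) {
      list(image = apply_normalization(s$image, stats), truth = s$truth)
    })
    vel_net <- params_scale(net$params, 0)
    vel_pw <- params_scale(pw$params, 0)
    vel_mu <- mu * 0
    trace <- data.frame(iteration = integer(), lr = numeric(), loss = numeric())
    for (it in seq_len(config$max_iter)) {
      smp <- maybe_augment(draw_sample(samples, it), config, it)
      fw <- net_forward(net, smp$image$data, cache = TRUE)
      cf <- crf_forward(fw$scores, smp$image$data, pw, mu, crf_cfg,
                        cache = TRUE)
      ce <- q_ce(cf$Q, as.integer(smp$truth))
      cb <- crf_backward(cf$cache, ce$g)
      bw <- net_backward(net, fw$cache, cb$gscores)
      lr <- learning_rate_at(config, it)
      st <- sgd_step(net$params, vel_net, bw$grads, lr, config$momentum,
                     config$weight_decay)
      net$params <- st$params
      vel_net <- st$vel
      stp <- sgd_step(pw$params, vel_pw, cb$gnet, lr, config$momentum,
                      config$weight_decay)
      pw$params <- stp$params
      vel_pw <- stp$vel
      vel_mu <- config$momentum * vel_mu -
        lr * (cb$gmu + config$weight_decay * mu)
      mu <- mu + vel_mu
      trace[nrow(trace) + 1L, ] <- list(it, lr, ce$loss)
    }
    return(structure(list(stage = stage, config = config, net = net, mu = mu,
                          pwnet = pw, crf = crf_cfg, stats = stats,
                          loss_trace = trace),
                     class = "scribbleseg_checkpoint"))
  }
  # stage == "rnet"
  if (is.null(prev) || prev$stage != "joint_pnet") {
    stop("ordering violation: rnet requires the joint_pnet (stage 1) checkpoint")
  }
  stats <- prev$stats
  nc <- n_channels(data[[1L]]$image)
  # frozen stage-1 model segments the training images; clicks are simulated
  # against ground truth; geodesic stacks are built once
  stacks <- vector("list", length(data))
  for (i in seq_along(data)) {
    im_n <- apply_normalization(data[[i]]$image, stats)
    seg1 <- segment_image(prev, data[[i]]$image)
    scr <- simulate_interactions(seg1$labels, data[[i]]$truth,
                                 rng_seed = config$rng_seed + i)
    stk <- encode_interactions(im_n, scr, seg1$prob,
                               rng_seed = config$rng_seed + i)
    stacks[[i]] <- list(x = stk, truth = data[[i]]$truth, scribbles = scr,
                        features = im_n$data)
  }
  rnet <- build_network(network_config(ndim = config$ndim,
                                       channels = config$channels,
                                       in_channels = nc + 3L),
                        seed = config$rng_seed + 1L)
  pw <- prev$pwnet
  mu <- compatibility_init(rnet$config$num_labels)
  crf_cfg <- crf_config(ndim = config$ndim,
                        num_labels = rnet$config$num_labels,
                        iterations = config$crf_iterations,
                        feature_dim = nc)
  vel_net <- params_scale(rnet$params, 0)
  vel_pw <- params_scale(pw$params, 0)
  vel_mu <- mu * 0
  trace <- data.frame(iteration = integer(), lr = numeric(), loss = numeric())
  n_pre <- as.integer(ceiling(config$max_iter * 2 / 3))
  for (it in seq_len(config$max_iter)) {
    smp <- draw_sample(stacks, it)
    fw <- net_forward(rnet, smp$x, cache = TRUE)
    lr <- learning_rate_at(config, it)
    if (it <= n_pre) {
      sc <- matrix(fw$scores, length(smp$truth), rnet$config$num_labels)
      ce <- softmax_ce(sc, as.integer(smp$truth))
      bw <- net_backward(rnet, fw$cache, array(ce$g, dim(fw$scores)))
    } else {
      cf <- crf_forward(fw$scores, array(smp$features, dim(smp$features)),
                        pw, mu, crf_cfg, scribbles = smp$scribbles,
                        cache = TRUE)
      ce <- q_ce(cf$Q, as.integer(smp$truth))
      cb <- crf_backward(cf$cache, ce$g)
      bw <- net_backward(rnet, fw$cache, cb$gscores)
      stp <- sgd_step(pw$params, vel_pw, cb$gnet, lr, config$momentum,
                      config$weight_decay)
      pw$params <- stp$params
      vel_pw <- stp$vel
      vel_mu <- config$momentum * vel_mu -
        lr * (cb$gmu + config$weight_decay * mu)
      mu <- mu + vel_mu
    }
    st <- sgd_step(rnet$params, vel_net, bw$grads, lr, config$momentum,
                   config$weight_decay)
    rnet$params <- st$params
    vel_net <- st$vel
    trace[nrow(trace) + 1L, ] <- list(it, lr, ce$loss)
  }
  structure(list(stage = "rnet", config = config, net = rnet, mu = mu,
                 pwnet = pw, crf = crf_cfg, stats = stats,
                 loss_trace = trace),
            class = "scribbleseg_checkpoint")
}
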