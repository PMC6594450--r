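#' Dilated convolution
#'
#' Convolution of a multi-channel grid with a dilated kernel: kernel taps are
#' spaced `q` grid steps apart, the stride is 1, and zero padding of width
#' `q*r` keeps the output extent equal to the input extent. With `q = 1` this
#' is ordinary convolution.
#'
#' @param x Input: matrix, or array `(n1, n2, C_in)` / `(n1, n2, n3, C_in)`.
#' @param kernel Kernel of edge `2r + 1`: matrix, or array
#'   `(k, k, C_in, C_out)` in 2D / `(k, k, k, C_in, C_out)` in 3D.
#' @param q Dilation parameter (>= 1).
#' @param bias Per-output-channel bias, default 0.
#' @return Output grid with the same spatial extent as the input.
#' @export
dilated_convolution <- function(x, kernel, q = 1L, bias = NULL) {
  stopifnot(q >= 1L)
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L)
  if (is.matrix(kernel)) dim(kernel) <- c(dim(kernel), 1L, 1L)
  nd_x <- length(dim(x))
  nd_k <- length(dim(kernel))
  if (nd_x == 3L && nd_k == 3L) dim(kernel) <- c(dim(kernel), 1L)
  if (nd_x == 4L && nd_k == 4L) dim(kernel) <- c(dim(kernel), 1L)
  co <- dim(kernel)[length(dim(kernel))]
  if (is.null(bias)) bias <- rep(0, co)
  y <- if (nd_x == 3L) {
    cpp_conv2d(x, kernel, bias, as.integer(q))
  } else if (nd_x == 4L) {
    cpp_conv3d(x, kernel, bias, as.integer(q))
  } else {
    stop("x must be a 2D or 3D (optionally multi-channel) grid")
  }
  if (dim(y)[length(dim(y))] == 1L) {
    dim(y) <- head(dim(y), -1L)
  }
  y
}

#' Network configuration
#'
#' Describes the resolution-preserving proposal (P-Net) and refinement
#' (R-Net) architectures: five dilated-convolution blocks whose features are
#' concatenated, followed by a two-layer 1x1 classifier. Kernels have edge
#' `2r + 1` and block `i` uses dilation `d * 2^(i-1)`. The 3D variant
#' downsamples once before the blocks, compresses each block's features by
#' `compression_3d` with 1x1x1 convolutions before concatenation, and
#' upsamples the final scores back to the input extent.
#'
#' @param ndim Spatial dimensionality, 2 or 3.
#' @param r Kernel half-width (default 1, i.e. 3x3 kernels).
#' @param d Base dilation parameter (default 1).
#' @param tau Convolution layers per block; must have 5 entries
#'   (default `c(2, 2, 3, 3, 3)`).
#' @param channels Output channels per block: default 64 in 2D, 16 in 3D.
#' @param in_channels Input channels: `C_I` for P-Net, `C_I + 3` for R-Net.
#' @param num_labels Number of output labels L (default 2).
#' @param downsample_3d Apply the single 3D downsampling stage (default TRUE
#'   for 3D, ignored in 2D).
#' @param compression_3d 3D per-block feature compression factor (default 4).
#' @param hidden_cls Width of the first 1x1 classifier layer (defaults to
#'   `channels`).
#' @return A `network_config` object.
#' @export
network_config <- function(ndim = 2L, r = 1L, d = 1L, tau = c(2L, 2L, 3L, 3L, 3L),
                           channels = NULL, in_channels = 1L, num_labels = 2L,
                           downsample_3d = NULL, compression_3d = 4L,
                           hidden_cls = NULL) {
  ndim <- as.integer(ndim)
  stopifnot(ndim %in% c(2L, 3L), r >= 1L, d >= 1L, length(tau) == 5L,
            all(tau >= 1L), in_channels >= 1L, num_labels >= 2L)
  if (is.null(channels)) channels <- if (ndim == 2L) 64L else 16L
  stopifnot(channels >= 1L)
  if (is.null(downsample_3d)) downsample_3d <- ndim == 3L
  if (ndim == 3L && channels %% compression_3d != 0L) {
    stop("configuration error: channels must be divisible by compression_3d")
  }
  if (is.null(hidden_cls)) hidden_cls <- channels
  structure(list(ndim = ndim, r = as.integer(r), d = as.integer(d),
                 tau = as.integer(tau), channels = as.integer(channels),
                 in_channels = as.integer(in_channels),
                 num_labels = as.integer(num_labels),
                 downsample_3d = isTRUE(downsample_3d),
                 compression_3d = as.integer(compression_3d),
                 hidden_cls = as.integer(hidden_cls)),
            class = "network_config")
}

#' Per-block dilation schedule
#'
#' Block `i` uses dilation `q_i = d * 2^(i-1)`.
#' @param config A `network_config`.
#' @return Integer vector `q_1..q_5`.
#' @export
dilation_schedule <- function(config) {
  as.integer(config$d * 2^(0:4))
}

#' Receptive-field edge length of a block
#'
#' The receptive field of block `i` is a square (cube) of edge
#' `R_i = 2 * sum_{j<=i} tau_j * r * q_j + 1`. With `r = 1` this gives the
#' closed forms `4d+1, 12d+1, 36d+1, 84d+1, 180d+1` for blocks 1..5.
#'
#' @param config A `network_config`.
#' @param block_index Block number in 1..5.
#' @return Edge length in pixels (of the resolution-preserving grid).
#' @export
receptive_field <- function(config, block_index) {
  if (!all(block_index %in% 1:5)) {
    stop("invalid block: block_index must be in 1..5")
  }
  q <- dilation_schedule(config)
  vapply(block_index, function(b) {
    2 * sum(config$tau[1:b] * config$r * q[1:b]) + 1
  }, numeric(1))
}

he_init <- function(dims, fan_in) {
  array(rnorm(prod(dims), sd = sqrt(2 / fan_in)), dims)
}

conv_param <- function(k, ci, co, ndim) {
  wd <- c(rep(k, ndim), ci, co)
  # small positive bias keeps narrow networks from starting with dead
  # rectified channels (He-initialized weights, zero input -> zero pre-act)
  list(w = he_init(wd, k^ndim * ci), b = rep(0.01, co))
}

#' Build a P-Net/R-Net style network
#'
#' Instantiates the executable network described by `config` with He-style
#' seeded initialization: five resolution-preserving dilated blocks
#' (rectified-linear after every convolution), multi-scale concatenation of
#' the block outputs (compressed by 1x1x1 convolutions in 3D), and a
#' two-layer 1x1 classifier emitting per-pixel, per-label scores. P-Net and
#' R-Net differ only in `in_channels`.
#'
#' @param config A `network_config`.
#' @param seed Integer seed for weight initialization.
#' @return A `dilated_net` object with elements `config` and `params`.
#' @export
build_network <- function(config, seed = 1L) {
  stopifnot(inherits(config, "network_config"))
  k <- 2L * config$r + 1L
  params <- with_seed(seed, {
    blocks <- vector("list", 5L)
    ci <- config$in_channels
    for (b in 1:5) {
      blocks[[b]] <- vector("list", config$tau[b])
      for (l in seq_len(config$tau[b])) {
        blocks[[b]][[l]] <- conv_param(k, ci, config$channels, config$ndim)
        ci <- config$channels
      }
    }
    comp <- NULL
    concat_ch <- 5L * config$channels
    if (config$ndim == 3L) {
      cc <- config$channels %/% config$compression_3d
      comp <- lapply(1:5, function(b) {
        conv_param(1L, config$channels, cc, config$ndim)
      })
      concat_ch <- 5L * cc
    }
    cls1 <- conv_param(1L, concat_ch, config$hidden_cls, config$ndim)
    cls2 <- conv_param(1L, config$hidden_cls, config$num_labels, config$ndim)
    list(blocks = blocks, comp = comp, cls1 = cls1, cls2 = cls2)
  })
  structure(list(config = config, params = params), class = "dilated_net")
}

#' @export
print.dilated_net <- function(x, ...) {
  cat(sprintf("<dilated_net> %dD, %d->%d channels, C=%d, d=%d, blocks (%s)\n",
              x$config$ndim, x$config$in_channels, x$config$num_labels,
              x$config$channels, x$config$d,
              paste(x$config$tau, collapse = ",")))
  invisible(x)
}

#' Layer-by-layer description of a network
#'
#' A serializable plan: per layer (kernel size, output channels, dilation),
#' the concatenation over blocks 1..5, and the 1x1 classifier pair.
#'
#' @param net A `dilated_net`.
#' @return A list suitable for [write_network_spec()].
#' @export
network_spec <- function(net) {
  cfg <- net$config
  q <- dilation_schedule(cfg)
  k <- 2L * cfg$r + 1L
  layers <- list()
  for (b in 1:5) {
    for (l in seq_len(cfg$tau[b])) {
      layers[[length(layers) + 1L]] <- list(
        block = b, kernel = k, out_channels = cfg$channels, dilation = q[b])
    }
  }
  list(dimensionality = cfg$ndim,
       in_channels = cfg$in_channels,
       num_labels = cfg$num_labels,
       blocks = layers,
       concatenation = list(blocks = 1:5,
                            compression = if (cfg$ndim == 3L) cfg$compression_3d else 1L),
       classifier = list(list(kernel = 1L, out_channels = cfg$hidden_cls, dilation = 1L),
                         list(kernel = 1L, out_channels = cfg$num_labels, dilation = 1L)),
       downsample = cfg$ndim == 3L && cfg$downsample_3d)
}

conv_fwd <- function(x, p, q, ndim) {
  if (ndim == 2L) cpp_conv2d(x, p$w, p$b, as.integer(q))
  else cpp_conv3d(x, p$w, p$b, as.integer(q))
}

conv_bwd <- function(x, p, gy, q, ndim) {
  if (ndim == 2L) cpp_conv2d_grad(x, p$w, gy, as.integer(q))
  else cpp_conv3d_grad(x, p$w, gy, as.integer(q))
}

bind_channels <- function(arrs) {
  sp <- head(dim(arrs[[1]]), -1L)
  chans <- vapply(arrs, function(a) dim(a)[length(dim(a))], integer(1))
  out <- array(0, c(sp, sum(chans)))
  off <- 0L
  flat <- prod(sp)
  for (a in arrs) {
    out[off * flat + seq_len(flat * dim(a)[length(dim(a))])] <- a
    off <- off + dim(a)[length(dim(a))]
  }
  out
}

#' Run a network forward
#'
#' @param net A `dilated_net`.
#' @param x Input array `(spatial extent, in_channels)`; the channel
#'   dimension is required even when `in_channels = 1`.
#' @param cache Keep intermediate activations for [net_backward()].
#' @return List with `scores` (array `(spatial extent, num_labels)`) and,
#'   when requested, `cache`.
#' @export
net_forward <- function(net, x, cache = FALSE) {
  cfg <- net$config
  ndim <- cfg$ndim
  if (length(dim(x)) != ndim + 1L || dim(x)[ndim + 1L] != cfg$in_channels) {
    stop("configuration error: input channel count does not match the network")
  }
  q <- dilation_schedule(cfg)
  full_extent <- head(dim(x), -1L)
  h <- x
  if (ndim == 3L && cfg$downsample_3d) h <- cpp_avgpool3d(h)
  inputs <- list()   # input to each conv layer, flat order
  preacts <- list()  # pre-activation outputs (ReLU masks)
  block_out <- vector("list", 5L)
  li <- 0L
  for (b in 1:5) {
    for (l in seq_len(cfg$tau[b])) {
      li <- li + 1L
      inputs[[li]] <- h
      y <- conv_fwd(h, net$params$blocks[[b]][[l]], q[b], ndim)
      preacts[[li]] <- y
      h <- relu(y)
    }
    block_out[[b]] <- h
  }
  comp_pre <- comp_out <- NULL
  if (ndim == 3L) {
    comp_pre <- comp_out <- vector("list", 5L)
    for (b in 1:5) {
      y <- conv_fwd(block_out[[b]], net$params$comp[[b]], 1L, ndim)
      comp_pre[[b]] <- y
      comp_out[[b]] <- relu(y)
    }
    concat <- bind_channels(comp_out)
  } else {
    concat <- bind_channels(block_out)
  }
  y1 <- conv_fwd(concat, net$params$cls1, 1L, ndim)
  h1 <- relu(y1)
  scores_small <- conv_fwd(h1, net$params$cls2, 1L, ndim)
  scores <- scores_small
  if (ndim == 3L && cfg$downsample_3d) {
    scores <- cpp_upsample3d(scores_small, as.integer(full_extent))
  }
  out <- list(scores = scores)
  if (cache) {
    out$cache <- list(inputs = inputs, preacts = preacts,
                      block_out = block_out, comp_pre = comp_pre,
                      comp_out = comp_out, concat = concat, y1 = y1, h1 = h1,
                      small_extent = head(dim(scores_small), -1L),
                      full_extent = full_extent)
  }
  out
}

#' Back-propagate through a network
#'
#' @param net A `dilated_net`.
#' @param cache Cache from `net_forward(..., cache = TRUE)`.
#' @param gscores Gradient of the loss with respect to the scores.
#' @return List with `grads` (same structure as `net$params`) and `gx`
#'   (gradient with respect to the input; `NULL` for the downsampled 3D
#'   variant, whose pooling stage is the first operation).
#' @export
net_backward <- function(net, cache, gscores) {
  cfg <- net$config
  ndim <- cfg$ndim
  q <- dilation_schedule(cfg)
  g <- gscores
  if (ndim == 3L && cfg$downsample_3d) {
    g <- cpp_upsample3d_grad(gscores, as.integer(cache$small_extent))
  }
  grads <- list(blocks = vector("list", 5L), comp = NULL, cls1 = NULL, cls2 = NULL)
  r2 <- conv_bwd(cache$h1, net$params$cls2, g, 1L, ndim)
  grads$cls2 <- list(w = r2$gw, b = r2$gb)
  gh1 <- r2$gx * (cache$y1 > 0)
  r1 <- conv_bwd(cache$concat, net$params$cls1, gh1, 1L, ndim)
  grads$cls1 <- list(w = r1$gw, b = r1$gb)
  gconcat <- r1$gx
  # split concat gradient back into per-block slices
  sp <- head(dim(gconcat), -1L)
  flat <- prod(sp)
  slice_ch <- if (ndim == 3L) cfg$channels %/% cfg$compression_3d else cfg$channels
  gblock_out <- vector("list", 5L)
  if (ndim == 3L) grads$comp <- vector("list", 5L)
  for (b in 1:5) {
    gsl <- array(gconcat[(b - 1L) * slice_ch * flat + seq_len(slice_ch * flat)],
                 c(sp, slice_ch))
    if (ndim == 3L) {
      gcomp <- gsl * (cache$comp_pre[[b]] > 0)
      rc <- conv_bwd(cache$block_out[[b]], net$params$comp[[b]], gcomp, 1L, ndim)
      grads$comp[[b]] <- list(w = rc$gw, b = rc$gb)
      gblock_out[[b]] <- rc$gx
    } else {
      gblock_out[[b]] <- gsl
    }
  }
  li <- length(cache$inputs)
  gh <- gblock_out[[5L]]
  for (b in 5:1) {
    grads$blocks[[b]] <- vector("list", cfg$tau[b])
    for (l in rev(seq_len(cfg$tau[b]))) {
      gpre <- gh * (cache$preacts[[li]] > 0)
      rr <- conv_bwd(cache$inputs[[li]], net$params$blocks[[b]][[l]], gpre,
                     q[b], ndim)
      grads$blocks[[b]][[l]] <- list(w = rr$gw, b = rr$gb)
      gh <- rr$gx
      li <- li - 1L
    }
    if (b > 1L) gh <- gh + gblock_out[[b - 1L]]
  }
  gx <- if (ndim == 3L && cfg$downsample_3d) NULL else gh
  list(grads = grads, gx = gx)
}

#' Serialize a network description to YAML
#' @param net A `dilated_net`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_network_spec <- function(net, path) {
  yaml::write_yaml(network_spec(net), path)
  invisible(path)
}
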