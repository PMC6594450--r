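# Seeded synthetic images: smooth blobs (or ellipses) on a darker
# background, with additive Gaussian noise and an optional low-frequency
# multiplicative intensity inhomogeneity. These emulate the low-contrast,
# ambiguous-boundary regime that motivates interactive refinement; they make
# no attempt at imaging physics or anatomy.

#' Fixture configuration
#'
#' @param ndim Spatial dimensionality, 2 or 3.
#' @param extent Per-axis extent (scalar recycled); each axis >= 16.
#' @param shape `"blob"` (thresholded band-limited noise; ambiguous
#'   boundaries) or `"ellipse"` (geometric primitive).
#' @param contrast Foreground-background mean intensity gap before noise
#'   (> 0).
#' @param noise Additive Gaussian noise standard deviation (>= 0).
#' @param inhomogeneity Amplitude of a zero-mean low-frequency multiplicative
#'   field (0 disables).
#' @param background Background intensity level.
#' @param fg_fraction Approximate foreground area fraction for blob shapes.
#' @param rng_seed Integer seed; all randomness flows through it.
#' @return A `fixture_config` object.
#' @export
fixture_config <- function(ndim = 2L, extent = 64L, shape = c("blob", "ellipse"),
                           contrast = 0.5, noise = 0.1, inhomogeneity = 0.2,
                           background = 0.2, fg_fraction = 0.25,
                           rng_seed = 1L) {
  shape <- match.arg(shape)
  ndim <- as.integer(ndim)
  extent <- as.integer(rep(extent, length.out = ndim))
  stopifnot(ndim %in% c(2L, 3L), all(extent >= 16L), contrast > 0, noise >= 0,
            inhomogeneity >= 0, fg_fraction > 0, fg_fraction < 1)
  structure(list(ndim = ndim, extent = extent, shape = shape,
                 contrast = contrast, noise = noise,
                 inhomogeneity = inhomogeneity, background = background,
                 fg_fraction = fg_fraction, rng_seed = as.integer(rng_seed)),
            class = "fixture_config")
}

# Separable Gaussian smoothing via banded weight matrices (reflect-free:
# weights renormalized at the borders).
smooth_gaussian <- function(arr, sigma) {
  dims <- dim(arr)
  nd <- length(dims)
  axis_mat <- function(n) {
    half <- max(1L, ceiling(3 * sigma))
    idx <- seq_len(n)
    W <- outer(idx, idx, function(i, j) {
      w <- dnorm(j - i, sd = sigma)
      w[abs(j - i) > half] <- 0
      w
    })
    W / rowSums(W)
  }
  out <- arr
  for (d in seq_len(nd)) {
    W <- axis_mat(dims[d])
    perm <- c(d, seq_len(nd)[-d])
    m <- matrix(aperm(out, perm), dims[d])
    m <- W %*% m
    out <- aperm(array(m, dims[perm]), order(perm))
  }
  out
}

#' Generate a synthetic image and its ground-truth mask
#'
#' The foreground mean exceeds the background mean by `contrast` before
#' noise; the mask is exactly the generating shape; output is reproducible
#' under the configured seed.
#'
#' @param config A `fixture_config`.
#' @return List with `image` (an `image_volume`) and `truth` (integer mask).
#' @export
make_image <- function(config) {
  stopifnot(inherits(config, "fixture_config"))
  ext <- config$extent
  with_seed(config$rng_seed, {
    mask <- if (config$shape == "blob") {
      z <- array(rnorm(prod(ext)), ext)
      zs <- smooth_gaussian(z, sigma = min(ext) / 10)
      thr <- quantile(zs, 1 - config$fg_fraction)
      (zs > thr) * 1L
    } else {
      coords <- grid_coords(ext)
      ctr <- ext / 2 + runif(config$ndim, -0.1, 0.1) * ext
      ax <- runif(config$ndim, 0.15, 0.3) * ext
      v <- rowSums(sweep(sweep(coords, 2L, ctr, `-`), 2L, ax, `/`)^2)
      array(as.integer(v <= 1), ext)
    }
    img <- config$background + config$contrast * mask
    if (config$inhomogeneity > 0) {
      f <- smooth_gaussian(array(rnorm(prod(ext)), ext), sigma = min(ext) / 4)
      f <- f - mean(f)
      f <- f / max(abs(f), 1e-12)
      img <- img * (1 + config$inhomogeneity * f)
    }
    if (config$noise > 0) img <- img + rnorm(prod(ext), sd = config$noise)
    storage.mode(mask) <- "integer"
    list(image = image_volume(array(img, ext), ndim = config$ndim),
         truth = mask)
  })
}

binary_dilate <- function(mask) {
  m <- mask > 0
  offs <- neighbour_offsets(length(dim(m)), "face")
  out <- m
  for (o in seq_len(nrow(offs))) out <- out | shift_pull(m, offs[o, ], FALSE)
  out * 1L
}

binary_erode <- function(mask) {
  m <- mask > 0
  offs <- neighbour_offsets(length(dim(m)), "face")
  out <- m
  for (o in seq_len(nrow(offs))) out <- out & shift_pull(m, offs[o, ], FALSE)
  out * 1L
}

#' Corrupt a ground-truth mask in a controlled way
#'
#' Produces mis-segmentations of a predictable size class for testing click
#' simulation and refinement: morphological erosion/dilation (face
#' structuring element, `magnitude` iterations), a rigid shift by
#' `magnitude` pixels along a random axis, or dropping one random connected
#' component.
#'
#' @param truth Non-empty binary array.
#' @param mode `"erode"`, `"dilate"`, `"shift"`, or `"drop-component"`.
#' @param magnitude Integer strength; 0 returns `truth` unchanged.
#' @param rng_seed Seed for the random choices of `"shift"` and
#'   `"drop-component"`.
#' @return Corrupted integer mask, deterministic under the seed.
#' @export
degrade_segmentation <- function(truth, mode = c("erode", "dilate", "shift",
                                                 "drop-component"),
                                 magnitude = 1L, rng_seed = 1L) {
  mode <- match.arg(mode)
  if (sum(truth > 0) == 0L) stop("truth mask is empty")
  if (magnitude == 0L && mode != "drop-component") {
    return(truth * 1L)
  }
  m <- truth * 1L
  dims <- dim(m)
  with_seed(rng_seed, {
    switch(mode,
      erode = {
        for (i in seq_len(magnitude)) m <- binary_erode(m)
        m
      },
      dilate = {
        for (i in seq_len(magnitude)) m <- binary_dilate(m)
        m
      },
      shift = {
        ax <- sample.int(length(dims), 1L)
        sgn <- sample(c(-1L, 1L), 1L)
        off <- integer(length(dims))
        off[ax] <- sgn * magnitude
        shift_pull(m, off, 0L) * 1L
      },
      `drop-component` = {
        offs <- neighbour_offsets(length(dims), "face")
        lab <- cpp_label_components(as.integer(m > 0), as.integer(dims), offs)
        k <- max(lab)
        drop_id <- sample.int(k, 1L)
        m[lab == drop_id] <- 0L
        m
      })
  })
}
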