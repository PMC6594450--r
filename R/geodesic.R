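#' Geodesic distance transform of a seed set
#'
#' Computes, for every pixel, the unsigned geodesic distance to the nearest
#' seed: the minimum over paths of the accumulated intensity change along the
#' path. On the discrete grid a path steps between 8-connected (2D) or
#' 26-connected (3D) neighbours and each step costs the Euclidean norm of the
#' channel-wise intensity difference — there is no additive spatial term, so
#' a constant image yields an identically zero map and voxel anisotropy does
#' not enter. Distances are computed by the raster-scan algorithm: forward
#' and backward sweeps with a 3x3 (2D) or 3x3x3 (3D) kernel, repeated in
#' pairs. In `"converged"` mode pass pairs repeat until no distance changes
#' by more than `tol` (up to `max_pairs`), which makes the result match the
#' exact shortest-path distance on the neighbour graph; `"fast"` runs a
#' single pair as a cheap approximation.
#'
#' @param image An `image_volume` (or array coercible to one).
#' @param seeds Integer matrix of 1-based seed coordinates, one per row.
#' @param mode `"converged"` (default) or `"fast"`.
#' @param tol Convergence tolerance on the largest per-pass distance change.
#' @param max_pairs Cap on forward+backward pass pairs in converged mode.
#' @return A `geodesic_map`: list with `distances` (spatial array),
#'   `source_label`, `valid`, `pairs`, `converged`.
#' @export
geodesic_distance <- function(image, seeds, mode = c("converged", "fast"),
                              tol = 1e-6, max_pairs = 20L) {
  mode <- match.arg(mode)
  image <- as_image_volume(image)
  seeds <- as.matrix(seeds)
  if (nrow(seeds) == 0L) stop("no seeds: the seed set is empty")
  if (ncol(seeds) != image$ndim) {
    stop("invalid scribble: seed coordinates have wrong dimensionality")
  }
  extent <- spatial_extent(image)
  if (any(seeds < 1L) || any(sweep(seeds, 2L, extent, `>`))) {
    stop("invalid scribble: seed index outside the image extent")
  }
  storage.mode(seeds) <- "integer"
  pairs <- if (mode == "fast") 1L else as.integer(max_pairs)
  res <- if (image$ndim == 2L) {
    cpp_geodesic2d(image$data, seeds - 1L, tol, pairs)
  } else {
    cpp_geodesic3d(image$data, seeds - 1L, tol, pairs)
  }
  geodesic_map(res$dist, source_label = NA_character_, valid = TRUE,
               pairs = res$pairs, converged = res$converged)
}

#' Construct a geodesic map object
#'
#' @param distances Spatial array of non-negative distances (or random fill
#'   when `valid = FALSE`).
#' @param source_label `"foreground"`, `"background"`, or `NA`.
#' @param valid `TRUE` for computed maps, `FALSE` for random-filled
#'   placeholders used when a scribble class is empty.
#' @param pairs,converged Raster-scan diagnostics.
#' @return A `geodesic_map` object.
#' @export
geodesic_map <- function(distances, source_label = NA_character_,
                         valid = TRUE, pairs = NA_integer_,
                         converged = NA) {
  structure(list(distances = distances, source_label = source_label,
                 valid = valid, pairs = pairs, converged = converged),
            class = "geodesic_map")
}

#' @export
print.geodesic_map <- function(x, ...) {
  cat(sprintf("<geodesic_map> %s, %s, extent %s\n",
              x$source_label, if (x$valid) "computed" else "random fill",
              paste(dim(x$distances), collapse = "x")))
  invisible(x)
}

# Euclidean analogue kept only for ablation (distance to the nearest seed in
# index space, ignoring intensities).
euclidean_seed_distance <- function(extent, seeds) {
  coords <- grid_coords(extent)
  d2 <- matrix(Inf, nrow(coords), 1L)
  for (s in seq_len(nrow(seeds))) {
    ds <- rowSums(sweep(coords, 2L, seeds[s, ], `-`)^2)
    d2 <- pmin(d2, ds)
  }
  array(sqrt(d2), extent)
}

#' Assemble the refinement-network input stack
#'
#' Concatenates, in this fixed channel order: the image channels, the initial
#' segmentation (foreground probability by default), the foreground geodesic
#' map, and the background geodesic map — giving `C_I + 3` channels. Each
#' computed geodesic channel is rescaled so its image-wise maximum is 1; when
#' a scribble class is empty its channel is filled with seeded uniform random
#' values on \[0, 1\] so it shares the value range of normalized maps.
#'
#' @param image An `image_volume`.
#' @param scribbles A `scribble_set` (either class may be empty).
#' @param initial_segmentation Spatial array congruent with the image:
#'   foreground probability (default) or binary labels.
#' @param rng_seed Integer seed driving the random fill of absent channels.
#' @param seg_channel `"probability"` or `"binary"` — how the initial
#'   segmentation channel is encoded.
#' @param normalize Rescale valid geodesic maps by their maximum (default).
#' @param encoding `"geodesic"` (default) or `"euclidean"` (ablation only).
#' @param geodesic_mode Passed to [geodesic_distance()].
#' @return Array with dimensions `(spatial extent, C_I + 3)`, plus an
#'   attribute `"channel_valid"` marking which of the two interaction
#'   channels hold computed maps.
#' @export
encode_interactions <- function(image, scribbles, initial_segmentation,
                                rng_seed,
                                seg_channel = c("probability", "binary"),
                                normalize = TRUE,
                                encoding = c("geodesic", "euclidean"),
                                geodesic_mode = "converged") {
  seg_channel <- match.arg(seg_channel)
  encoding <- match.arg(encoding)
  image <- as_image_volume(image)
  extent <- spatial_extent(image)
  seg <- initial_segmentation
  if (!identical(as.integer(dim(seg) %||% length(seg)), as.integer(extent))) {
    stop("incompatible inputs: initial segmentation extent differs from the image")
  }
  if (seg_channel == "binary") seg <- (seg >= 0.5) * 1.0
  # both interaction channels draw from one seeded stream, in fixed order
  interaction_channel <- function(seed_matrix, label, rng) {
    if (nrow(seed_matrix) == 0L) {
      vals <- array(rng(prod(extent)), extent)
      return(geodesic_map(vals, source_label = label, valid = FALSE))
    }
    if (encoding == "euclidean") {
      d <- euclidean_seed_distance(extent, seed_matrix)
      gm <- geodesic_map(d, source_label = label, valid = TRUE)
    } else {
      gm <- geodesic_distance(image, seed_matrix, mode = geodesic_mode)
      gm$source_label <- label
    }
    if (normalize) {
      mx <- max(gm$distances)
      if (is.finite(mx) && mx > 0) gm$distances <- gm$distances / mx
    }
    gm
  }
  maps <- with_seed(rng_seed, {
    fg <- interaction_channel(scribbles$foreground, "foreground", runif)
    bg <- interaction_channel(scribbles$background, "background", runif)
    list(fg = fg, bg = bg)
  })
  out <- array(0, c(extent, n_channels(image) + 3L))
  nc <- n_channels(image)
  flat <- prod(extent)
  out[seq_len(flat * nc)] <- image$data
  out[flat * nc + seq_len(flat)] <- seg
  out[flat * (nc + 1L) + seq_len(flat)] <- maps$fg$distances
  out[flat * (nc + 2L) + seq_len(flat)] <- maps$bg$distances
  attr(out, "channel_valid") <- c(foreground = maps$fg$valid,
                                  background = maps$bg$valid)
  out
}
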