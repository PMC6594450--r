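#' Image volumes
#'
#' An `image_volume` is the basic intensity container: a 2D image or 3D
#' volume with one or more channels, plus voxel spacing and a world origin.
#' Internally the data are held as a column-major array whose last dimension
#' is the channel axis: `(n1, n2, C)` in 2D, `(n1, n2, n3, C)` in 3D.
#'
#' @param data Numeric matrix or array of intensities. A matrix is taken as a
#'   single-channel 2D image. For a 3-dimensional array, `ndim` disambiguates
#'   between a multi-channel 2D image (`ndim = 2`, last axis = channels) and a
#'   single-channel 3D volume (`ndim = 3`).
#' @param ndim Spatial dimensionality, 2 or 3. May be omitted when
#'   unambiguous.
#' @param spacing Physical grid step per spatial axis (mm); defaults to 1.
#' @param origin World coordinate of grid index 1 (mm); defaults to 0.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(data, ndim = NULL, spacing = NULL, origin = NULL) {
  if (is.matrix(data)) {
    ndim <- 2L
    dim(data) <- c(dim(data), 1L)
  } else if (is.array(data)) {
    nd_arr <- length(dim(data))
    if (nd_arr == 2L) {
      ndim <- 2L
      dim(data) <- c(dim(data), 1L)
    } else if (nd_arr == 3L) {
      if (is.null(ndim)) {
        stop("3-dimensional array is ambiguous: give ndim = 2 (multi-channel image) or ndim = 3 (volume)")
      }
      if (ndim == 3L) dim(data) <- c(dim(data), 1L)
    } else if (nd_arr == 4L) {
      ndim <- 3L
    } else {
      stop("data must have 2 to 4 dimensions")
    }
  } else {
    stop("data must be a numeric matrix or array")
  }
  ndim <- as.integer(ndim)
  stopifnot(ndim %in% c(2L, 3L))
  extent <- dim(data)[seq_len(ndim)]
  if (any(extent < 1L)) stop("all spatial extents must be >= 1")
  if (is.null(spacing)) spacing <- rep(1, ndim)
  if (is.null(origin)) origin <- rep(0, ndim)
  if (length(spacing) != ndim || any(spacing <= 0)) {
    stop("spacing must be strictly positive with one entry per spatial axis")
  }
  if (length(origin) != ndim) stop("origin must have one entry per spatial axis")
  structure(
    list(data = data, ndim = ndim, spacing = as.numeric(spacing),
         origin = as.numeric(origin)),
    class = "image_volume"
  )
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume> %dD, extent %s, %d channel(s), spacing %s mm\n",
              x$ndim, paste(spatial_extent(x), collapse = "x"),
              n_channels(x), paste(format(x$spacing), collapse = "x")))
  invisible(x)
}

#' Spatial extent of an image volume
#' @param x An `image_volume`.
#' @return Integer vector of per-axis extents.
#' @export
spatial_extent <- function(x) dim(x$data)[seq_len(x$ndim)]

#' Number of channels of an image volume
#' @param x An `image_volume`.
#' @return Integer channel count.
#' @export
n_channels <- function(x) dim(x$data)[x$ndim + 1L]

as_image_volume <- function(x, ndim = NULL) {
  if (inherits(x, "image_volume")) x else image_volume(x, ndim = ndim)
}

#' Extract one channel of an image volume
#' @param x An `image_volume`.
#' @param c Channel index (default 1).
#' @return The channel's spatial array (no channel dimension).
#' @export
channel_data <- function(x, c = 1L) {
  idx <- c(rep(list(quote(expr = )), x$ndim), list(c))
  arr <- do.call(`[`, c(list(x$data), idx, list(drop = FALSE)))
  dim(arr) <- spatial_extent(x)
  arr
}

#' Scribble sets
#'
#' A `scribble_set` carries user interactions: disjoint sets of foreground
#' and background grid indices, each a matrix with one 1-based coordinate per
#' row (2 or 3 columns).
#'
#' @param foreground,background Integer matrices of grid coordinates (may
#'   have zero rows).
#' @param extent Optional spatial extent used to range-check the indices.
#' @return An object of class `scribble_set`.
#' @export
scribble_set <- function(foreground = NULL, background = NULL, extent = NULL) {
  norm <- function(m, nd) {
    if (is.null(m) || length(m) == 0L) {
      return(matrix(integer(), 0L, nd %||% 2L))
    }
    m <- as.matrix(m)
    storage.mode(m) <- "integer"
    dimnames(m) <- NULL
    m
  }
  nd <- NULL
  if (!is.null(foreground) && length(foreground)) nd <- ncol(as.matrix(foreground))
  if (is.null(nd) && !is.null(background) && length(background)) {
    nd <- ncol(as.matrix(background))
  }
  if (is.null(nd)) nd <- if (is.null(extent)) 2L else length(extent)
  fg <- norm(foreground, nd)
  bg <- norm(background, nd)
  if (ncol(fg) != ncol(bg)) stop("foreground and background dimensionality differ")
  if (!is.null(extent)) {
    chk <- function(m) {
      if (nrow(m) == 0L) return(TRUE)
      all(m >= 1L) && all(sweep(m, 2L, extent, `<=`))
    }
    if (!chk(fg) || !chk(bg)) stop("invalid scribble: index outside the image extent")
    key <- function(m) flat_index(m, extent)
    if (length(intersect(key(fg), key(bg)))) {
      stop("inconsistent constraints: pixel present in both scribble classes")
    }
  } else if (nrow(fg) && nrow(bg)) {
    kf <- apply(fg, 1L, paste, collapse = ",")
    kb <- apply(bg, 1L, paste, collapse = ",")
    if (length(intersect(kf, kb))) {
      stop("inconsistent constraints: pixel present in both scribble classes")
    }
  }
  structure(list(foreground = fg, background = bg), class = "scribble_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.scribble_set <- function(x, ...) {
  cat(sprintf("<scribble_set> %d foreground, %d background pixel(s)\n",
              nrow(x$foreground), nrow(x$background)))
  invisible(x)
}

#' Number of scribbled pixels
#' @param x A `scribble_set`.
#' @return Total count over both classes.
#' @export
n_scribbles <- function(x) nrow(x$foreground) + nrow(x$background)

#' Convert a label mask to a scribble set
#'
#' The on-disk scribble convention is a single-channel mask congruent with
#' the image: 0 = unlabeled, 1 = foreground, 2 = background.
#'
#' @param mask Integer array with values in \{0, 1, 2\}.
#' @return A `scribble_set`.
#' @export
scribbles_from_mask <- function(mask) {
  dims <- dim(mask)
  fg <- which(mask == 1L, arr.ind = TRUE)
  bg <- which(mask == 2L, arr.ind = TRUE)
  scribble_set(fg, bg, extent = dims)
}

#' Convert a scribble set to a label mask
#' @param scribbles A `scribble_set`.
#' @param extent Spatial extent of the target mask.
#' @return Integer array with 0 = unlabeled, 1 = foreground, 2 = background.
#' @export
scribbles_to_mask <- function(scribbles, extent) {
  mask <- array(0L, extent)
  if (nrow(scribbles$foreground)) mask[scribbles$foreground] <- 1L
  if (nrow(scribbles$background)) mask[scribbles$background] <- 2L
  mask
}

#' Merge two scribble sets
#'
#' Used for accumulating interactions across refinement rounds.
#' @param a,b `scribble_set` objects.
#' @param extent Optional extent for validation.
#' @return The union `scribble_set`; a pixel scribbled in both classes is an
#'   error.
#' @export
merge_scribbles <- function(a, b, extent = NULL) {
  scribble_set(rbind(a$foreground, b$foreground),
               rbind(a$background, b$background), extent = extent)
}
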