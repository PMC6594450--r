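# File formats: PNG for 2D (8-bit, grayscale or multi-channel without
# alpha), NIfTI for 3D (spacing carried in pixdim). Intensities are mapped
# to floating point on read; PNG values live on the [0, 1] grid of the bit
# depth, NIfTI values are stored as-is.

is_nifti_path <- function(path) grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)
is_png_path <- function(path) grepl("\\.png$", path, ignore.case = TRUE)

#' Read an image from disk
#'
#' PNG files become 2D `image_volume`s (values in \[0, 1\]); NIfTI files
#' (`.nii`/`.nii.gz`) become 2D or 3D volumes with their stored spacing.
#' PNGs with an alpha channel are rejected.
#'
#' @param path Input file path.
#' @return An `image_volume`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("I/O error: file not found: ", path)
  if (is_png_path(path)) {
    m <- png::readPNG(path)
    if (length(dim(m)) == 3L && dim(m)[3L] %in% c(2L, 4L)) {
      stop("I/O error: PNG alpha channels are unsupported")
    }
    return(image_volume(m, ndim = 2L))
  }
  if (is_nifti_path(path)) {
    img <- RNifti::readNifti(path)
    arr <- as.array(img)
    nd <- length(dim(arr))
    if (!nd %in% c(2L, 3L)) {
      stop("I/O error: only 2D/3D single-channel NIfTI images are supported")
    }
    sp <- RNifti::pixdim(img)[seq_len(nd)]
    return(image_volume(arr, ndim = nd, spacing = sp))
  }
  stop("I/O error: unknown image format: ", path)
}

#' Write an image to disk
#'
#' PNG output requires values in \[0, 1\] (quantized to 8 bits); NIfTI
#' output is lossless floating point and preserves the spacing.
#'
#' @param image An `image_volume` (or spatial array).
#' @param path Output path ending in `.png`, `.nii`, or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  image <- as_image_volume(image, ndim = if (is_png_path(path)) 2L else NULL)
  if (is_png_path(path)) {
    if (image$ndim != 2L) stop("I/O error: PNG supports 2D images only")
    arr <- image$data
    if (min(arr) < 0 || max(arr) > 1) {
      stop("I/O error: PNG intensities must lie in [0, 1]; rescale first")
    }
    if (dim(arr)[3L] == 1L) dim(arr) <- dim(arr)[1:2]
    png::writePNG(arr, path)
    return(invisible(path))
  }
  if (is_nifti_path(path)) {
    arr <- image$data
    if (dim(arr)[length(dim(arr))] == 1L) dim(arr) <- head(dim(arr), -1L)
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- image$spacing
    RNifti::writeNifti(img, path)
    return(invisible(path))
  }
  stop("I/O error: unknown image format: ", path)
}

#' Read a scribble mask
#'
#' Scribble masks are single-channel images congruent with the target
#' image: 0 = unlabeled, 1 = foreground, 2 = background (PNG stores the
#' codes as value/255).
#'
#' @param path Input path.
#' @return A `scribble_set`.
#' @export
read_scribbles <- function(path) {
  img <- read_image(path)
  arr <- channel_data(img, 1L)
  codes <- if (is_png_path(path)) round(arr * 255) else round(arr)
  if (!all(codes %in% 0:2)) {
    stop("I/O error: scribble mask must contain only codes 0, 1, 2")
  }
  scribbles_from_mask(array(as.integer(codes), dim(codes)))
}

#' Write a scribble mask
#' @param scribbles A `scribble_set`.
#' @param extent Spatial extent of the mask.
#' @param path Output path (`.png` for 2D, `.nii`/`.nii.gz` for 3D).
#' @return `path`, invisibly.
#' @export
write_scribbles <- function(scribbles, extent, path) {
  mask <- scribbles_to_mask(scribbles, extent)
  if (is_png_path(path)) {
    write_image(image_volume(array(mask / 255, dim(mask)), ndim = 2L), path)
  } else {
    write_image(image_volume(array(as.numeric(mask), dim(mask)),
                             ndim = length(dim(mask))), path)
  }
  invisible(path)
}

#' Export a geodesic map for inspection
#'
#' Writes the floating-point distances as NIfTI (works for both 2D and 3D
#' maps).
#' @param map A `geodesic_map`.
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
export_geodesic_map <- function(map, path) {
  stopifnot(inherits(map, "geodesic_map"))
  if (!is_nifti_path(path)) stop("I/O error: geodesic maps export as NIfTI")
  arr <- map$distances
  write_image(image_volume(arr, ndim = length(dim(arr))), path)
}

# Stable short hash of a configuration object (FNV-1a over its serialized
# bytes); identifies which settings produced a checkpoint.
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2L))
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    # xor only touches the low byte; multiply mod 2^32 in 16-bit halves so
    # every intermediate stays exactly representable in a double
    h <- h - (h %% 256) + bitwXor(h %% 256, b)
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- (lo * p + ((hi * p) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Save a checkpoint
#'
#' Persists a training checkpoint (or any model bundle) together with the
#' package version and a hash of its configuration.
#' @param checkpoint The object to save.
#' @param path Destination `.rds` path.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(checkpoint, path) {
  bundle <- list(
    checkpoint = checkpoint,
    manifest = list(
      package_version = as.character(utils::packageVersion("scribbleseg")),
      config_hash = config_hash(checkpoint$config),
      saved_at = format(Sys.time(), tz = "UTC")
    )
  )
  saveRDS(bundle, path)
  invisible(path)
}

#' Load a checkpoint
#' @param path Path written by [save_checkpoint()].
#' @return The checkpoint object, with the manifest in attribute
#'   `"manifest"`.
#' @export
load_checkpoint <- function(path) {
  bundle <- readRDS(path)
  ck <- bundle$checkpoint
  if (!is.null(ck$config) &&
      !identical(config_hash(ck$config), bundle$manifest$config_hash)) {
    stop("I/O error: checkpoint config hash mismatch")
  }
  attr(ck, "manifest") <- bundle$manifest
  ck
}
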