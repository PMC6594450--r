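#' Dice overlap coefficient
#'
#' `2 |A intersect B| / (|A| + |B|)` for two binary regions.
#' @param seg Binary array: the segmentation.
#' @param truth Binary array: the reference.
#' @return Dice score in \[0, 1\].
#' @export
dice <- function(seg, truth) {
  if (!identical(dim(seg), dim(truth))) {
    stop("incompatible inputs: mask extents differ")
  }
  a <- seg > 0
  b <- truth > 0
  denom <- sum(a) + sum(b)
  if (denom == 0L) stop("undefined Dice: both masks are empty")
  2 * sum(a & b) / denom
}

#' Surface points of a binary region
#'
#' Region pixels with at least one face-adjacent neighbour outside the
#' region; the image border counts as outside, so a region touching the
#' border has surface there.
#'
#' @param mask Binary array.
#' @return Coordinate matrix (one 1-based grid index per row).
#' @export
surface_points <- function(mask) {
  m <- mask > 0
  nd <- length(dim(m))
  offs <- neighbour_offsets(nd, "face")
  outside <- array(FALSE, dim(m))
  for (o in seq_len(nrow(offs))) {
    outside <- outside | !shift_pull(m, offs[o, ], fill = FALSE)
  }
  which(m & outside, arr.ind = TRUE)
}

#' Average symmetric surface distance
#'
#' The mean, over all surface points of both masks, of the Euclidean
#' distance to the nearest surface point of the other mask. Distances are in
#' pixel index units unless `spacing` is given (then mm).
#'
#' @param seg Binary array: the segmentation.
#' @param truth Binary array: the reference.
#' @param spacing Optional physical voxel spacing per axis.
#' @return Non-negative ASSD value.
#' @export
assd <- function(seg, truth, spacing = NULL) {
  if (!identical(dim(seg), dim(truth))) {
    stop("incompatible inputs: mask extents differ")
  }
  if (sum(seg > 0) == 0L || sum(truth > 0) == 0L) {
    stop("undefined ASSD: empty mask")
  }
  sa <- surface_points(seg)
  sb <- surface_points(truth)
  if (!is.null(spacing)) {
    sa <- sweep(sa, 2L, spacing, `*`)
    sb <- sweep(sb, 2L, spacing, `*`)
  }
  nearest <- function(from, to) {
    # chunked all-pairs nearest distance; surface sets are small
    apply(from, 1L, function(p) {
      sqrt(min(rowSums(sweep(to, 2L, p, `-`)^2)))
    })
  }
  (sum(nearest(sa, sb)) + sum(nearest(sb, sa))) / (nrow(sa) + nrow(sb))
}

#' Score segmentation/truth mask pairs
#'
#' @param pairs List of `list(seg = , truth = )` binary arrays, or two
#'   parallel lists via `seg` and `truth`.
#' @param spacing Optional spacing passed to [assd()].
#' @return A data frame with one row per pair: `dice`, `assd`.
#' @export
score_pairs <- function(pairs, spacing = NULL) {
  res <- lapply(pairs, function(p) {
    c(dice = dice(p$seg, p$truth),
      assd = tryCatch(assd(p$seg, p$truth, spacing),
                      error = function(e) NA_real_))
  })
  as.data.frame(do.call(rbind, res))
}
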