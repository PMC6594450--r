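#' Find mis-segmented regions
#'
#' Compares an automatic segmentation with the ground truth and returns the
#' connected components of the disagreement: under-segmented regions are
#' missed foreground (`truth & !auto`), over-segmented regions are spurious
#' foreground (`auto & !truth`). Components use face connectivity
#' (4-connected in 2D, 6-connected in 3D) by default.
#'
#' @param auto_seg Binary array: the automatic segmentation.
#' @param ground_truth Binary array congruent with `auto_seg`.
#' @param connectivity `"face"` (default) or `"full"` (8/26-connected).
#' @return A list of `misseg_region` objects, each with `kind`
#'   (`"under"`/`"over"`), `pixels` (coordinate matrix), and `size`.
#' @export
find_misseg_regions <- function(auto_seg, ground_truth,
                                connectivity = c("face", "full")) {
  connectivity <- match.arg(connectivity)
  dims <- dim(auto_seg)
  if (!identical(dims, dim(ground_truth))) {
    stop("incompatible inputs: segmentation and ground truth extents differ")
  }
  nd <- length(dims)
  offs <- neighbour_offsets(nd, connectivity)
  collect <- function(mask, kind) {
    lab <- cpp_label_components(as.integer(mask), as.integer(dims), offs)
    k <- max(lab)
    lapply(seq_len(k), function(i) {
      px <- which(lab == i, arr.ind = TRUE)
      structure(list(kind = kind, pixels = px, size = nrow(px)),
                class = "misseg_region")
    })
  }
  under <- collect(ground_truth > 0 & !(auto_seg > 0), "under")
  over <- collect(auto_seg > 0 & !(ground_truth > 0), "over")
  c(under, over)
}

#' @export
print.misseg_region <- function(x, ...) {
  cat(sprintf("<misseg_region> %s-segmented, %d pixel(s)\n", x$kind, x$size))
  invisible(x)
}

#' Number of simulated clicks for a region of size N_m
#'
#' Zero when `N_m < 30`, otherwise `ceiling(N_m / 100)`.
#' @param n_m Region size(s) in pixels.
#' @return Integer click count(s).
#' @export
click_count <- function(n_m) {
  ifelse(n_m < 30, 0L, as.integer(ceiling(n_m / 100)))
}

#' Simulate clicks for one mis-segmented region
#'
#' Samples [click_count()] pixels uniformly without replacement from the
#' region. Under-segmented regions yield foreground clicks, over-segmented
#' regions background clicks.
#'
#' @param region A `misseg_region`.
#' @param rng_seed Integer seed.
#' @return List with `pixels` (coordinate matrix of the sampled clicks) and
#'   `label` (`"foreground"`/`"background"`).
#' @export
clicks_for_region <- function(region, rng_seed) {
  if (region$size == 0L) stop("region is empty")
  n <- click_count(region$size)
  rows <- if (n == 0L) integer() else with_seed(rng_seed, {
    sample.int(region$size, n)
  })
  list(pixels = region$pixels[rows, , drop = FALSE],
       label = if (region$kind == "under") "foreground" else "background")
}

#' Simulate user interactions on a segmentation
#'
#' Full click simulation used to supervise the refinement stage: find all
#' mis-segmented regions, draw the per-region click budget, and return the
#' union as a `scribble_set` (foreground clicks on missed foreground,
#' background clicks on spurious foreground). Deterministic under a fixed
#' seed; regions are visited in component-label order with one RNG stream.
#'
#' @param auto_seg Binary array: the automatic segmentation.
#' @param ground_truth Binary array congruent with `auto_seg`.
#' @param rng_seed Integer seed.
#' @param connectivity Component connectivity, see [find_misseg_regions()].
#' @param dilate_radius Optional radius turning point clicks into small
#'   scribble blobs (0 = single-pixel clicks).
#' @return A `scribble_set`.
#' @export
simulate_interactions <- function(auto_seg, ground_truth, rng_seed,
                                  connectivity = "face", dilate_radius = 0L) {
  regions <- find_misseg_regions(auto_seg, ground_truth, connectivity)
  dims <- dim(auto_seg)
  fg <- bg <- NULL
  with_seed(rng_seed, {
    for (reg in regions) {
      n <- click_count(reg$size)
      if (n == 0L) next
      rows <- sample.int(reg$size, n)
      px <- reg$pixels[rows, , drop = FALSE]
      if (reg$kind == "under") fg <- rbind(fg, px) else bg <- rbind(bg, px)
    }
  })
  if (dilate_radius > 0L) {
    grow <- function(px, source_mask) {
      if (is.null(px) || nrow(px) == 0L) return(px)
      m <- array(0L, dims)
      m[px] <- 1L
      for (i in seq_len(dilate_radius)) m <- binary_dilate(m)
      # scribbles stay inside their source region so labels remain correct
      which(m > 0L & source_mask, arr.ind = TRUE)
    }
    fg <- grow(fg, ground_truth > 0 & !(auto_seg > 0))
    bg <- grow(bg, auto_seg > 0 & !(ground_truth > 0))
  }
  scribble_set(fg, bg, extent = dims)
}
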