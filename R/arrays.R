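# Internal array utilities shared across modules. Images are column-major R
# arrays with the channel as the last dimension: (n1, n2, C) in 2D and
# (n1, n2, n3, C) in 3D. Spatial-only maps (masks, distance maps) drop the
# channel dimension.

# Evaluate `code` with the global RNG seeded to `seed`, restoring the caller's
# RNG state afterwards so library calls never perturb user-level randomness.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Row-wise softmax with max-shift stabilisation.
row_softmax <- function(s) {
  m <- apply(s, 1L, max)
  e <- exp(s - m)
  e / rowSums(e)
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

# All integer coordinates of a grid with the given spatial extent, as an
# n_pix x nd matrix in column-major (flat index) order.
grid_coords <- function(dims) {
  nd <- length(dims)
  args <- lapply(dims, seq_len)
  as.matrix(do.call(expand.grid, args))[, seq_len(nd), drop = FALSE]
}

# Flat (column-major) index of 1-based coordinate rows; NA when out of range.
flat_index <- function(coords, dims) {
  nd <- length(dims)
  ok <- rep(TRUE, nrow(coords))
  for (d in seq_len(nd)) {
    ok <- ok & coords[, d] >= 1L & coords[, d] <= dims[d]
  }
  idx <- coords[, 1L]
  mult <- 1L
  for (d in seq_len(nd)[-1L]) {
    mult <- mult * dims[d - 1L]
    idx <- idx + (coords[, d] - 1L) * mult
  }
  idx[!ok] <- NA_integer_
  idx
}

# Shift a spatial array by an integer offset: out[i] = arr[i + off], with
# `fill` outside the grid. Used for surfaces, morphology and CRF messages.
shift_pull <- function(arr, off, fill = 0) {
  dims <- dim(arr)
  if (is.null(dims)) dims <- length(arr)
  out <- array(fill, dims)
  src <- dst <- vector("list", length(dims))
  for (d in seq_along(dims)) {
    o <- off[d]
    lo <- max(1L, 1L - o)
    hi <- min(dims[d], dims[d] - o)
    if (lo > hi) return(out)
    dst[[d]] <- lo:hi
    src[[d]] <- (lo + o):(hi + o)
  }
  out[matrix_index(dst, dims)] <- arr[matrix_index(src, dims)]
  out
}

# Flat indices of the Cartesian product of per-axis index vectors.
matrix_index <- function(idx_list, dims) {
  g <- do.call(expand.grid, idx_list)
  flat_index(as.matrix(g), dims)
}

# Unit face offsets (2*nd) or full neighbourhood offsets (3^nd - 1).
neighbour_offsets <- function(nd, connectivity = c("face", "full")) {
  connectivity <- match.arg(connectivity)
  if (connectivity == "face") {
    out <- matrix(0L, 2L * nd, nd)
    for (d in seq_len(nd)) {
      out[2L * d - 1L, d] <- 1L
      out[2L * d, d] <- -1L
    }
    return(out)
  }
  g <- as.matrix(do.call(expand.grid, rep(list(-1L:1L), nd)))
  g[rowSums(abs(g)) > 0L, , drop = FALSE]
}
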