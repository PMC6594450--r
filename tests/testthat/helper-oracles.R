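# Independent oracles used by the tests. These deliberately share no code
# with the package implementation: Dijkstra on the explicit neighbour graph,
# nested-summation convolution, a scalar transcription of the mean-field
# update, and all-pairs surface distances.

# Exact shortest-path geodesic distances on the 8/26-connected pixel graph
# with edge weight |I(i) - I(j)|, by Dijkstra's algorithm.
oracle_geodesic <- function(img, seeds) {
  dims <- dim(img)
  nd <- length(dims)
  offs <- as.matrix(do.call(expand.grid, rep(list(-1:1), nd)))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  co <- as.matrix(do.call(expand.grid, lapply(dims, seq_len)))
  n <- prod(dims)
  flat <- function(m) {
    idx <- m[, 1]
    mult <- 1
    for (d in seq_len(nd)[-1]) {
      mult <- mult * dims[d - 1]
      idx <- idx + (m[, d] - 1) * mult
    }
    idx
  }
  d <- rep(Inf, n)
  d[flat(seeds)] <- 0
  done <- rep(FALSE, n)
  for (it in seq_len(n)) {
    u <- which.min(ifelse(done, Inf, d))
    if (!is.finite(d[u])) break
    done[u] <- TRUE
    for (o in seq_len(nrow(offs))) {
      v <- co[u, ] + offs[o, ]
      if (any(v < 1) || any(v > dims)) next
      vi <- flat(matrix(v, 1))
      w <- abs(img[u] - img[vi])
      if (d[u] + w < d[vi]) d[vi] <- d[u] + w
    }
  }
  array(d, dims)
}

# Direct nested-summation dilated convolution (single channel).
oracle_conv2d <- function(x, w, q) {
  n1 <- nrow(x); n2 <- ncol(x)
  k <- nrow(w); r <- (k - 1) / 2
  y <- matrix(0, n1, n2)
  for (p1 in 1:n1) for (p2 in 1:n2) {
    for (a1 in -r:r) for (a2 in -r:r) {
      s1 <- p1 - q * a1; s2 <- p2 - q * a2
      if (s1 >= 1 && s1 <= n1 && s2 >= 1 && s2 <= n2) {
        y[p1, p2] <- y[p1, p2] + x[s1, s2] * w[a1 + r + 1, a2 + r + 1]
      }
    }
  }
  y
}

# Scalar transcription of the constrained mean-field update: explicit loops
# over pixels, labels, and patch neighbours; no message caching.
oracle_mean_field <- function(scores, feats, net, mu, cfg, iterations,
                              cons_idx = NULL, cons_lab = NULL) {
  dims <- head(dim(scores), -1L)
  L <- dim(scores)[length(dim(scores))]
  n <- prod(dims)
  co <- as.matrix(do.call(expand.grid, lapply(dims, seq_len)))
  half <- (cfg$patch - 1) %/% 2
  offs <- as.matrix(do.call(expand.grid, lapply(half, function(h) (-h):h)))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  flat <- function(v) {
    idx <- v[1]; mult <- 1
    for (d in seq_along(dims)[-1]) {
      mult <- mult * dims[d - 1]
      idx <- idx + (v[d] - 1) * mult
    }
    idx
  }
  S <- matrix(scores, n, L)
  fmat <- matrix(feats, n, cfg$feature_dim)
  constrain <- function(Q) {
    if (!is.null(cons_idx)) {
      for (k in seq_along(cons_idx)) {
        Q[cons_idx[k], ] <- 0
        Q[cons_idx[k], cons_lab[k] + 1] <- 1
      }
    }
    Q
  }
  softmax1 <- function(s) { e <- exp(s - max(s)); e / sum(e) }
  Q <- t(apply(S, 1, softmax1))
  Q <- constrain(Q)
  for (t in seq_len(iterations)) {
    phi <- matrix(0, n, L)
    for (i in 1:n) for (l in 1:L) {
      acc <- 0
      for (lp in 1:L) for (o in seq_len(nrow(offs))) {
        j <- co[i, ] + offs[o, ]
        if (any(j < 1) || any(j > dims)) next
        ji <- flat(j)
        fv <- pairwise_net_forward(net, matrix(c(fmat[i, ] - fmat[ji, ],
                                                 sqrt(sum(offs[o, ]^2))), 1))
        acc <- acc + mu[l, lp] * fv * Q[ji, lp]
      }
      phi[i, l] <- acc
    }
    Q <- constrain(t(apply(S - phi, 1, softmax1)))
  }
  Q
}

# All-pairs average symmetric surface distance from first principles.
oracle_assd <- function(seg, truth) {
  surf <- function(m) {
    m <- m > 0
    dims <- dim(m)
    nd <- length(dims)
    co <- which(m, arr.ind = TRUE)
    keep <- vapply(seq_len(nrow(co)), function(r) {
      for (d in seq_len(nd)) {
        for (s in c(-1, 1)) {
          nb <- co[r, ]
          nb[d] <- nb[d] + s
          if (any(nb < 1) || any(nb > dims)) return(TRUE)
          if (!m[matrix(nb, 1)]) return(TRUE)
        }
      }
      FALSE
    }, logical(1))
    co[keep, , drop = FALSE]
  }
  sa <- surf(seg)
  sb <- surf(truth)
  dmin <- function(from, to) {
    vapply(seq_len(nrow(from)), function(i) {
      sqrt(min(rowSums(sweep(to, 2, from[i, ], `-`)^2)))
    }, numeric(1))
  }
  (sum(dmin(sa, sb)) + sum(dmin(sb, sa))) / (nrow(sa) + nrow(sb))
}

# Small seeded blob datasets shared by training tests.
make_blob_set <- function(n, extent, seed0, noise = 0.15, contrast = 0.5) {
  lapply(seq_len(n), function(i) {
    make_image(fixture_config(ndim = 2L, extent = extent, contrast = contrast,
                              noise = noise, inhomogeneity = 0.2,
                              rng_seed = seed0 + i))
  })
}
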