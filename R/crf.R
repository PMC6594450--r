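#' CRF configuration
#'
#' Settings for the mean-field CRF with a learned freeform pairwise
#' potential. Pairwise connections link each pixel to every other pixel of a
#' local patch centred on it (the centre itself is excluded): 7x7 by default
#' in 2D and 5x5x3 in 3D. The per-pixel features entering the pairwise
#' function are the image intensity channels; `d_ij` is the Euclidean
#' distance between pixel indices in grid units.
#'
#' @param ndim Spatial dimensionality, 2 or 3.
#' @param num_labels Label count L (labels 0..L-1; for binary segmentation
#'   label 1 is foreground).
#' @param patch Odd patch extent per axis; defaults `c(7, 7)` in 2D,
#'   `c(5, 5, 3)` in 3D.
#' @param iterations Mean-field iterations T (default 5).
#' @param feature_dim Feature dimension F (number of intensity channels).
#' @param spacing_aware Measure `d_ij` in physical units using the image
#'   spacing instead of grid units.
#' @return A `crf_config` object.
#' @export
crf_config <- function(ndim = 2L, num_labels = 2L, patch = NULL,
                       iterations = 5L, feature_dim = 1L,
                       spacing_aware = FALSE) {
  ndim <- as.integer(ndim)
  stopifnot(ndim %in% c(2L, 3L), num_labels >= 2L, iterations >= 1L,
            feature_dim >= 1L)
  if (is.null(patch)) patch <- if (ndim == 2L) c(7L, 7L) else c(5L, 5L, 3L)
  patch <- as.integer(patch)
  stopifnot(length(patch) == ndim, all(patch %% 2L == 1L))
  structure(list(ndim = ndim, num_labels = as.integer(num_labels),
                 patch = patch, iterations = as.integer(iterations),
                 feature_dim = as.integer(feature_dim),
                 spacing_aware = isTRUE(spacing_aware)),
            class = "crf_config")
}

# Ordered neighbour offsets of the patch, centre excluded.
patch_offsets <- function(config) {
  half <- (config$patch - 1L) %/% 2L
  g <- as.matrix(do.call(expand.grid, lapply(half, function(h) (-h):h)))
  g <- g[rowSums(abs(g)) > 0L, , drop = FALSE]
  storage.mode(g) <- "integer"
  dimnames(g) <- NULL
  g
}

#' Initial label-compatibility matrix
#'
#' The Iverson-bracket form `mu(l, l') = [l != l']`: zero cost for equal
#' labels, unit cost otherwise. Trainable thereafter.
#' @param num_labels Label count L.
#' @return An L x L numeric matrix.
#' @export
compatibility_init <- function(num_labels) {
  matrix(1, num_labels, num_labels) - diag(num_labels)
}

#' Contrast-sensitive pre-training target for the pairwise potential
#'
#' `exp(-||ftilde||^2 / (2 sigma^2 F)) * omega / d`, the classical
#' contrast-sensitive pairwise weight that the freeform Pairwise-Net is
#' initialized towards.
#'
#' @param ftilde Feature difference: numeric vector of length F, or an
#'   `n x F` matrix for vectorized evaluation.
#' @param d Positive pixel distance(s).
#' @param sigma Contrast bandwidth (default 0.08).
#' @param omega Magnitude (default 0.5).
#' @return Numeric target value(s).
#' @export
pairwise_target <- function(ftilde, d, sigma = 0.08, omega = 0.5) {
  if (any(d <= 0)) stop("invalid distance: d must be > 0")
  if (!is.matrix(ftilde)) ftilde <- matrix(ftilde, nrow = 1L)
  F_dim <- ncol(ftilde)
  drop(exp(-rowSums(ftilde^2) / (2 * sigma^2 * F_dim)) * omega / d)
}

#' Create an untrained Pairwise-Net
#'
#' A fully connected map from the `(F + 1)`-vector `(ftilde, d)` to a scalar
#' potential, with hidden widths 32 and 16, tanh hidden activations, and a
#' linear output layer (trained potentials may be negative).
#'
#' A fixed diagonal input scaling precedes the first layer: feature
#' differences are multiplied by `1 / (2 * sigma_ref)` and the distance by
#' `1/8` (the upper end of realizable patch distances), so the
#' contrast-sensitive spike the net must represent has order-one width in
#' the scaled coordinates and is reachable from a standard initialization.
#'
#' @param feature_dim Feature dimension F.
#' @param seed Seed for He-style initialization.
#' @param sigma_ref Contrast bandwidth the input scaling is matched to
#'   (default 0.08, the pre-training target's bandwidth).
#' @return A `pairwise_net` object.
#' @export
pairwise_net <- function(feature_dim = 1L, seed = 1L, sigma_ref = 0.08) {
  d_in <- feature_dim + 1L
  input_scale <- c(rep(1 / (2 * sigma_ref), feature_dim), 1 / 8)
  params <- with_seed(seed, list(
    W1 = matrix(rnorm(d_in * 32L, sd = sqrt(2 / d_in)), d_in, 32L),
    b1 = rep(0, 32L),
    W2 = matrix(rnorm(32L * 16L, sd = sqrt(2 / 32)), 32L, 16L),
    b2 = rep(0, 16L),
    W3 = matrix(rnorm(16L, sd = sqrt(2 / 16)), 16L, 1L),
    b3 = 0
  ))
  structure(list(feature_dim = as.integer(feature_dim),
                 input_scale = input_scale, params = params),
            class = "pairwise_net")
}

#' Evaluate a Pairwise-Net
#' @param net A `pairwise_net`.
#' @param x Input matrix `n x (F + 1)`; columns are ftilde then d.
#' @param cache Keep hidden activations for [pairwise_net_backward()].
#' @return Numeric vector of n potentials (with `cache` attribute when
#'   requested).
#' @export
pairwise_net_forward <- function(net, x, cache = FALSE) {
  p <- net$params
  x <- sweep(x, 2L, net$input_scale, `*`)
  h1 <- tanh(sweep(x %*% p$W1, 2L, p$b1, `+`))
  h2 <- tanh(sweep(h1 %*% p$W2, 2L, p$b2, `+`))
  out <- drop(h2 %*% p$W3) + p$b3
  if (cache) attr(out, "cache") <- list(x = x, h1 = h1, h2 = h2)
  out
}

#' Back-propagate through a Pairwise-Net
#' @param net A `pairwise_net`.
#' @param cache The `cache` attribute from a forward pass.
#' @param gout Gradient of the loss with respect to each output.
#' @return List of parameter gradients matching `net$params`.
#' @export
pairwise_net_backward <- function(net, cache, gout) {
  p <- net$params
  g3 <- matrix(gout, ncol = 1L)
  gW3 <- t(cache$h2) %*% g3
  gb3 <- sum(g3)
  gh2 <- (g3 %*% t(p$W3)) * (1 - cache$h2^2)
  gW2 <- t(cache$h1) %*% gh2
  gb2 <- colSums(gh2)
  gh1 <- (gh2 %*% t(p$W2)) * (1 - cache$h1^2)
  gW1 <- t(cache$x) %*% gh1
  gb1 <- colSums(gh1)
  list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2, W3 = gW3, b3 = gb3)
}

#' Pre-train a Pairwise-Net towards the contrast-sensitive target
#'
#' Draws feature-difference samples from Normal(0, sd = 2) per feature
#' coordinate and pixel distances uniformly from the realizable range
#' \[1, 8\] (distances below one grid step never occur between distinct
#' pixels, and the `omega / d` target is unbounded as d tends to 0), labels
#' them with [pairwise_target()] (`sigma = 0.08`, `omega = 0.5`), and fits
#' the net by minibatch stochastic gradient descent on the quadratic loss.
#'
#' @param feature_dim Feature dimension F.
#' @param n_samples Training-set size (100000 at full scale; 10000 is the
#'   desk-scale profile).
#' @param rng_seed Seed for sample generation, initialization and SGD order.
#' @param sigma,omega Target parameters.
#' @param epochs,batch,lr,momentum SGD settings (minibatch SGD with
#'   momentum and a slow 1/(1 + 0.02 (epoch - 1)) rate decay).
#' @param n_holdout Size of the fresh held-out set used to report the final
#'   mean squared error.
#' @return List with the trained `net`, `mse_holdout`, and the per-epoch
#'   `loss_trace`.
#' @export
pretrain_pairwise_net <- function(feature_dim = 1L, n_samples = 100000L,
                                  rng_seed = 1L, sigma = 0.08, omega = 0.5,
                                  epochs = 60L, batch = 100L, lr = 0.02,
                                  momentum = 0.9, n_holdout = 10000L) {
  d_min <- 1
  d_max <- 8
  gen <- function(n) {
    x <- cbind(matrix(rnorm(n * feature_dim, sd = 2), n, feature_dim),
               runif(n, d_min, d_max))
    list(x = x, y = pairwise_target(x[, seq_len(feature_dim), drop = FALSE],
                                    x[, feature_dim + 1L], sigma, omega))
  }
  with_seed(rng_seed, {
    train <- gen(n_samples)
    hold <- gen(n_holdout)
    net <- pairwise_net(feature_dim, seed = sample.int(2^30, 1L))
    vel <- lapply(net$params, function(p) p * 0)
    trace <- numeric(epochs)
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n_samples)
      lr_ep <- lr / (1 + 0.02 * (ep - 1))
      tot <- 0
      for (s in seq(1L, n_samples, by = batch)) {
        idx <- ord[s:min(s + batch - 1L, n_samples)]
        xb <- train$x[idx, , drop = FALSE]
        yb <- train$y[idx]
        pred <- pairwise_net_forward(net, xb, cache = TRUE)
        err <- as.numeric(pred) - yb
        tot <- tot + sum(err^2)
        gr <- pairwise_net_backward(net, attr(pred, "cache"),
                                    2 * err / length(err))
        for (nm in names(net$params)) {
          vel[[nm]] <- momentum * vel[[nm]] - lr_ep * gr[[nm]]
          net$params[[nm]] <- net$params[[nm]] + vel[[nm]]
        }
      }
      trace[ep] <- tot / n_samples
    }
    pred_h <- pairwise_net_forward(net, hold$x)
    list(net = net, mse_holdout = mean((pred_h - hold$y)^2),
         loss_trace = trace)
  })
}

# Precompute, per image, everything the message passing reuses across
# iterations: neighbour index maps, validity masks, pairwise-net inputs.
crf_precompute <- function(features, config, spacing = NULL) {
  dims <- head(dim(features), -1L)
  F_dim <- dim(features)[length(dim(features))]
  stopifnot(F_dim == config$feature_dim)
  n_pix <- prod(dims)
  fmat <- matrix(features, n_pix, F_dim)
  offs <- patch_offsets(config)
  n_off <- nrow(offs)
  sp <- if (config$spacing_aware && !is.null(spacing)) spacing else rep(1, config$ndim)
  d_off <- sqrt(colSums((t(offs) * sp)^2))
  coords <- grid_coords(dims)
  idxp <- matrix(NA_integer_, n_pix, n_off)  # flat index of i+o, pad row n_pix+1
  valid <- matrix(FALSE, n_pix, n_off)
  X <- matrix(0, n_pix * n_off, F_dim + 1L)
  for (o in seq_len(n_off)) {
    tgt <- sweep(coords, 2L, offs[o, ], `+`)
    fi <- flat_index(tgt, dims)
    ok <- !is.na(fi)
    valid[, o] <- ok
    fi[!ok] <- n_pix + 1L
    idxp[, o] <- fi
    rows <- (o - 1L) * n_pix + seq_len(n_pix)
    fpad <- rbind(fmat, 0)
    X[rows, seq_len(F_dim)] <- fmat - fpad[fi, , drop = FALSE]
    X[rows, F_dim + 1L] <- d_off[o]
  }
  list(dims = dims, n_pix = n_pix, n_off = n_off, idxp = idxp, valid = valid,
       X = X, d_off = d_off)
}

constraint_rows <- function(scribbles, dims, num_labels) {
  if (is.null(scribbles) || n_scribbles(scribbles) == 0L) {
    return(NULL)
  }
  fg <- flat_index(scribbles$foreground, dims)
  bg <- flat_index(scribbles$background, dims)
  if (anyNA(fg) || anyNA(bg)) {
    stop("invalid scribble: index outside the image extent")
  }
  if (length(intersect(fg, bg))) {
    stop("inconsistent constraints: pixel present in both scribble classes")
  }
  # binary convention: label 1 = foreground, label 0 = background
  list(idx = c(fg, bg),
       label = c(rep(1L, length(fg)), rep(0L, length(bg))))
}

apply_constraints <- function(Q, cons) {
  if (is.null(cons)) return(Q)
  Q[cons$idx, ] <- 0
  Q[cbind(cons$idx, cons$label + 1L)] <- 1
  Q
}

#' Pairwise message for every pixel and label
#'
#' One message-passing plus compatibility-transform step: for pixel i and
#' label l, sums `mu(l, l') * f(f_i - f_j, d_ij) * Q_j(l')` over labels l'
#' and all patch neighbours j of i (ordered pairs, centre excluded).
#' Pairwise values are evaluated once per pixel/offset and reused; the
#' result equals naive per-pair evaluation.
#'
#' @param Q Matrix `n_pix x L` of current label distributions (column-major
#'   pixel order), or an array `(spatial, L)`.
#' @param features Array `(spatial, F)` of per-pixel features.
#' @param net A `pairwise_net`.
#' @param mu L x L compatibility matrix.
#' @param config A `crf_config`.
#' @return Matrix `n_pix x L` of messages `phi_p`.
#' @export
pairwise_message <- function(Q, features, net, mu, config) {
  pre <- crf_precompute(features, config)
  Fv <- pairwise_net_forward(net, pre$X)
  Fmat <- matrix(Fv, pre$n_pix, pre$n_off)
  Fmat[!pre$valid] <- 0
  if (is.array(Q) && length(dim(Q)) > 2L) {
    Q <- matrix(Q, pre$n_pix, config$num_labels)
  }
  message_pass(Q, Fmat, pre$idxp, mu)$phi
}

message_pass <- function(Q, Fmat, idxp, mu) {
  n_pix <- nrow(Q)
  L <- ncol(Q)
  Qpad <- rbind(Q, 0)
  M <- matrix(0, n_pix, L)
  for (o in seq_len(ncol(Fmat))) {
    M <- M + Fmat[, o] * Qpad[idxp[, o], , drop = FALSE]
  }
  list(M = M, phi = M %*% t(mu))
}

#' Run the mean-field CRF forward
#'
#' Initializes `Q` as the normalized exponential of the negated unary
#' potentials (`psi_u(l) = -score_l`, so `Q0 = softmax(scores)`), then runs
#' `iterations` mean-field updates: message passing, compatibility
#' transform, adding the unary potentials, normalizing, and finally
#' overwriting scribbled pixels to exact 0/1 (applied after every
#' normalization and to the initial state). The whole computation is
#' differentiable through [crf_backward()] with respect to the scores, `mu`,
#' and the Pairwise-Net parameters; constrained pixels pass no gradient.
#'
#' @param scores Array `(spatial, L)` of per-pixel network scores.
#' @param features Array `(spatial, F)` of pairwise features (image
#'   intensity channels).
#' @param net A `pairwise_net`.
#' @param mu L x L compatibility matrix.
#' @param config A `crf_config`.
#' @param scribbles Optional `scribble_set` of hard constraints.
#' @param iterations Override `config$iterations`.
#' @param cache Keep intermediates for [crf_backward()].
#' @return List with `Q` (matrix `n_pix x L`), `Q_array` (same as an array
#'   `(spatial, L)`), and optionally `cache`.
#' @export
crf_forward <- function(scores, features, net, mu, config, scribbles = NULL,
                        iterations = NULL, cache = FALSE) {
  dims <- head(dim(scores), -1L)
  L <- config$num_labels
  stopifnot(dim(scores)[length(dim(scores))] == L)
  T_iter <- as.integer(iterations %||% config$iterations)
  pre <- crf_precompute(features, config)
  stopifnot(identical(as.integer(pre$dims), as.integer(dims)))
  Fv <- pairwise_net_forward(net, pre$X)
  Fmat <- matrix(Fv, pre$n_pix, pre$n_off)
  Fmat[!pre$valid] <- 0
  S <- matrix(scores, pre$n_pix, L)
  cons <- constraint_rows(scribbles, dims, L)
  Q_list <- vector("list", T_iter + 1L)
  M_list <- vector("list", T_iter)
  Q <- apply_constraints(row_softmax(S), cons)
  Q_list[[1L]] <- Q
  for (t in seq_len(T_iter)) {
    mp <- message_pass(Q, Fmat, pre$idxp, mu)
    M_list[[t]] <- mp$M
    Q <- apply_constraints(row_softmax(S - mp$phi), cons)
    Q_list[[t + 1L]] <- Q
  }
  out <- list(Q = Q, Q_array = array(Q, c(dims, L)), iterations = T_iter)
  if (cache) {
    out$cache <- list(pre = pre, Fmat = Fmat, S = S, cons = cons,
                      Q_list = Q_list, M_list = M_list, mu = mu, net = net,
                      dims = dims, L = L, T_iter = T_iter)
  }
  out
}

#' Back-propagate through the unrolled mean-field iterations
#'
#' @param cache Cache from `crf_forward(..., cache = TRUE)`.
#' @param gQ Gradient of the loss with respect to the final `Q`
#'   (matrix `n_pix x L` or congruent array).
#' @return List with `gscores` (array shaped like the input scores), `gmu`,
#'   and `gnet` (Pairwise-Net parameter gradients).
#' @export
crf_backward <- function(cache, gQ) {
  pre <- cache$pre
  L <- cache$L
  n_pix <- pre$n_pix
  if (is.array(gQ) && length(dim(gQ)) > 2L) gQ <- matrix(gQ, n_pix, L)
  cons <- cache$cons
  mu <- cache$mu
  gS <- matrix(0, n_pix, L)
  gmu <- matrix(0, L, L)
  gF <- matrix(0, n_pix, pre$n_off)
  softmax_bwd <- function(Qt, g) {
    if (!is.null(cons)) g[cons$idx, ] <- 0
    Qt * (g - rowSums(g * Qt))
  }
  for (t in rev(seq_len(cache$T_iter))) {
    Qt <- cache$Q_list[[t + 1L]]
    Qprev <- cache$Q_list[[t]]
    ds <- softmax_bwd(Qt, gQ)
    gS <- gS + ds
    gphi <- -ds
    gM <- gphi %*% mu
    gmu <- gmu + t(gphi) %*% cache$M_list[[t]]
    Qpad <- rbind(Qprev, 0)
    gQprev <- matrix(0, n_pix + 1L, L)
    for (o in seq_len(pre$n_off)) {
      io <- pre$idxp[, o]
      gF[, o] <- gF[, o] + rowSums(gM * Qpad[io, , drop = FALSE])
      contrib <- cache$Fmat[, o] * gM
      gQprev[io, ] <- gQprev[io, , drop = FALSE] + contrib
    }
    gQ <- gQprev[seq_len(n_pix), , drop = FALSE]
  }
  ds0 <- softmax_bwd(cache$Q_list[[1L]], gQ)
  gS <- gS + ds0
  gF[!pre$valid] <- 0
  pred <- pairwise_net_forward(cache$net, pre$X, cache = TRUE)
  gnet <- pairwise_net_backward(cache$net, attr(pred, "cache"),
                                as.numeric(gF))
  list(gscores = array(gS, c(cache$dims, L)), gmu = gmu, gnet = gnet)
}

#' Mean-field state
#'
#' Bundles everything one mean-field update needs: the current per-pixel
#' distribution `Q`, the unary scores, the pairwise features, the
#' Pairwise-Net, the compatibility matrix, and the configuration.
#'
#' @param scores Array `(spatial, L)` of unary network scores.
#' @param features Array `(spatial, F)` of pairwise features.
#' @param net A `pairwise_net`.
#' @param mu L x L compatibility matrix.
#' @param config A `crf_config`.
#' @param scribbles Optional `scribble_set` applied as hard constraints from
#'   initialization onwards.
#' @return A `mean_field_state` with `Q` initialized from the unary scores.
#' @export
mean_field_state <- function(scores, features, net, mu, config,
                             scribbles = NULL) {
  dims <- head(dim(scores), -1L)
  L <- config$num_labels
  cons <- constraint_rows(scribbles, dims, L)
  S <- matrix(scores, prod(dims), L)
  Q <- apply_constraints(row_softmax(S), cons)
  structure(list(Q = Q, scores = scores, features = features, net = net,
                 mu = mu, config = config, scribbles = scribbles,
                 dims = dims),
            class = "mean_field_state")
}

#' Run mean-field iterations on a state
#'
#' Applies `iterations` constrained mean-field updates to `state$Q`: each
#' iteration recomputes the pairwise message from the current `Q`, combines
#' it with the unary potentials, normalizes, and re-imposes any scribble
#' hard constraints.
#'
#' @param state A `mean_field_state`.
#' @param scribbles Optional `scribble_set` overriding the state's
#'   constraints (`NULL` keeps them).
#' @param iterations Number of updates to apply.
#' @return The updated `mean_field_state`.
#' @export
mean_field_iterate <- function(state, scribbles = NULL, iterations = 1L) {
  stopifnot(inherits(state, "mean_field_state"))
  if (!is.null(scribbles)) state$scribbles <- scribbles
  cfg <- state$config
  cons <- constraint_rows(state$scribbles, state$dims, cfg$num_labels)
  pre <- crf_precompute(state$features, cfg)
  Fv <- pairwise_net_forward(state$net, pre$X)
  Fmat <- matrix(Fv, pre$n_pix, pre$n_off)
  Fmat[!pre$valid] <- 0
  S <- matrix(state$scores, pre$n_pix, cfg$num_labels)
  Q <- apply_constraints(state$Q, cons)
  for (t in seq_len(iterations)) {
    mp <- message_pass(Q, Fmat, pre$idxp, state$mu)
    Q <- apply_constraints(row_softmax(S - mp$phi), cons)
  }
  state$Q <- Q
  state
}

#' Refine unary scores with the mean-field CRF
#'
#' Wraps initialization plus `config$iterations` constrained mean-field
#' updates. Without scribbles this is the automatic-stage CRF; with
#' scribbles the user interactions are enforced exactly at every iteration
#' and in the returned distribution.
#'
#' @param scores Array `(spatial, L)` of per-pixel network scores.
#' @param image An `image_volume` supplying the pairwise intensity features.
#' @param scribbles Optional `scribble_set`.
#' @param config A `crf_config`.
#' @param net A `pairwise_net`.
#' @param mu L x L compatibility matrix.
#' @return List with `prob` (array `(spatial, L)`) and `labels` (integer
#'   array of argmax labels, 0-based).
#' @export
crf_refine <- function(scores, image, scribbles = NULL, config, net, mu) {
  image <- as_image_volume(image)
  res <- crf_forward(scores, image$data, net, mu, config,
                     scribbles = scribbles)
  lab <- max.col(res$Q, ties.method = "first") - 1L
  list(prob = res$Q_array, labels = array(lab, dim(res$Q_array)[-length(dim(res$Q_array))]))
}
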