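#' Automatic stage-1 segmentation
#'
#' Runs the stage-1 model (P-Net followed by the mean-field CRF without
#' constraints) on an image: the image is normalized with the training
#' statistics, scored by the network, and regularized by the CRF.
#'
#' @param model A `"joint_pnet"` checkpoint from [train_stage()] (or a
#'   `"pnet_pretrain"` checkpoint, in which case the raw softmax is
#'   returned without CRF smoothing).
#' @param image An `image_volume` (un-normalized).
#' @return List with `prob` (foreground-probability array), `labels`
#'   (binary array), and `Q` (full per-label distribution array).
#' @export
segment_image <- function(model, image) {
  image <- as_image_volume(image)
  im_n <- apply_normalization(image, model$stats)
  fw <- net_forward(model$net, im_n$data)
  ext <- spatial_extent(image)
  L <- model$net$config$num_labels
  if (is.null(model$mu)) {
    Q <- row_softmax(matrix(fw$scores, prod(ext), L))
    Q_arr <- array(Q, c(ext, L))
  } else {
    res <- crf_forward(fw$scores, im_n$data, model$pwnet, model$mu, model$crf)
    Q <- res$Q
    Q_arr <- res$Q_array
  }
  lab <- array(as.integer(max.col(Q, ties.method = "first") - 1L), ext)
  fg <- array(Q[, 2L], ext)
  list(prob = fg, labels = lab, Q = Q_arr)
}

#' Scribble-driven stage-2 refinement
#'
#' Builds the `C_I + 3` input stack (image, initial segmentation, foreground
#' and background geodesic maps), runs R-Net, and applies the mean-field CRF
#' with the scribbles as hard constraints, so scribbled pixels are honored
#' exactly in the output. Repeated refinement rounds pass the accumulated
#' scribble set.
#'
#' @param model An `"rnet"` checkpoint from [train_stage()].
#' @param image An `image_volume` (un-normalized).
#' @param initial_prob Foreground-probability array from the previous round
#'   (stage-1 output, or an earlier refinement).
#' @param scribbles A `scribble_set`; either class may be empty (its
#'   geodesic channel is then random-filled from `rng_seed`).
#' @param rng_seed Seed for random-filled interaction channels.
#' @return List with `prob`, `labels`, and `Q` as in [segment_image()].
#' @export
refine_image <- function(model, image, initial_prob, scribbles,
                         rng_seed = 1L) {
  image <- as_image_volume(image)
  im_n <- apply_normalization(image, model$stats)
  stack <- encode_interactions(im_n, scribbles, initial_prob,
                               rng_seed = rng_seed)
  fw <- net_forward(model$net, stack)
  res <- crf_forward(fw$scores, im_n$data, model$pwnet, model$mu, model$crf,
                     scribbles = if (n_scribbles(scribbles) > 0L) scribbles)
  ext <- spatial_extent(image)
  lab <- array(as.integer(max.col(res$Q, ties.method = "first") - 1L), ext)
  list(prob = array(res$Q[, 2L], ext), labels = lab, Q = res$Q_array)
}

#' Train the full two-stage pipeline at desk scale
#'
#' Convenience wrapper running the complete protocol in order: P-Net
#' pre-training, Pairwise-Net pre-training, joint P-Net + CRF training, and
#' R-Net + constrained-CRF training on simulated interactions.
#'
#' @param data Training samples: list of `list(image, truth)`.
#' @param ndim Spatial dimensionality.
#' @param desk_scale Iteration-count divisor (see [train_config()]).
#' @param channels Network block width C.
#' @param crf_iterations Unrolled mean-field iterations during training.
#' @param rng_seed Master seed.
#' @param augment_enabled Augmentation switch for P-Net pre-training.
#' @return List with the four checkpoints: `pnet`, `pairwise`, `stage1`,
#'   `stage2`.
#' @export
train_full_pipeline <- function(data, ndim = 2L, desk_scale = 200,
                                channels = NULL, crf_iterations = 2L,
                                rng_seed = 1L, augment_enabled = TRUE) {
  cfg <- function(stage) {
    train_config(stage, ndim = ndim, desk_scale = desk_scale,
                 channels = channels, crf_iterations = crf_iterations,
                 rng_seed = rng_seed, augment_enabled = augment_enabled)
  }
  pnet <- train_stage(cfg("pnet_pretrain"), data)
  pairwise <- train_stage(cfg("pairwise_pretrain"), data)
  stage1 <- train_stage(cfg("joint_pnet"), data, prev = pnet,
                        pairwise = pairwise)
  stage2 <- train_stage(cfg("rnet"), data, prev = stage1)
  list(pnet = pnet, pairwise = pairwise, stage1 = stage1, stage2 = stage2)
}
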