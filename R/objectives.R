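# ---------------------------------------------------------------------------
# Training objectives.
#
# The generator is trained with four terms:
#   content      L_c   = mean |x - zhat_s|                       (pixel L1)
#   perceptual   L_p   = ||F(x) - F(zhat_s)||^2 / (C*H*W)  under a frozen
#                        feature backbone F
#   adversarial  L_adv = E[(D(T(zhat_s)) - 1)^2]
#   unsupervised L_us  = E[(D(T(zhat_s)) - D(T(zhat_u)))^2]
# combined as L_G = L_c + lambda_adv L_adv + lambda_us L_us + lambda_p L_p.
# The discriminator minimizes the least-squares objective
#   L_D = 1/2 E[(D(T(x)) - 1)^2] + 1/2 E[D(T(zhat_s))^2]
# with the 0-1 coding: fake label a = 0, real label b = 1, generator target
# c = 1.
# ---------------------------------------------------------------------------

#' Least-squares GAN coding constants
#'
#' Fake label `a = 0`, real label `b = 1`, generator target `c = 1`.
#'
#' @return named list with `a`, `b`, `c`
#' @export
lsgan_coding <- function() list(a = 0, b = 1, c = 1)

#' Loss weights for the generator objective
#'
#' Defaults are the published training weights.
#'
#' @param lambda_adv adversarial weight (default 0.1)
#' @param lambda_us unsupervised weight (default 0.01)
#' @param lambda_p perceptual weight (default 0.02)
#' @return a `loss_weights` list
#' @export
loss_weights <- function(lambda_adv = 0.1, lambda_us = 0.01,
                         lambda_p = 0.02) {
  stopifnot(lambda_adv >= 0, lambda_us >= 0, lambda_p >= 0)
  structure(list(lambda_adv = lambda_adv, lambda_us = lambda_us,
                 lambda_p = lambda_p), class = "loss_weights")
}

#' Pixel-wise L1 content loss
#'
#' @param tape autodiff tape
#' @param x,zhat nodes of equal shape (clear target, generator output)
#' @return scalar node: mean absolute difference
#' @export
content_loss <- function(tape, x, zhat) {
  if (!identical(dim(x$value), dim(zhat$value))) {
    stop("content_loss: shape mismatch")
  }
  op_mean(tape, op_abs(tape, op_sub(tape, x, zhat)))
}

#' Perceptual loss under a frozen feature backbone
#'
#' Squared Euclidean distance between backbone features of the two images,
#' normalized by the feature extent C*H*W (per sample, averaged over the
#' batch).
#'
#' @param tape autodiff tape
#' @param x,zhat image nodes of equal shape
#' @param backbone a feature backbone, e.g. [feature_backbone()]
#' @return scalar node
#' @export
perceptual_loss <- function(tape, x, zhat, backbone) {
  fx <- backbone$fwd(tape, x)
  fz <- backbone$fwd(tape, zhat)
  if (!identical(dim(fx$value), dim(fz$value))) {
    stop("perceptual_loss: feature shape mismatch")
  }
  d <- dim(fx$value)
  chw <- prod(d[1:3])
  # mean over all elements * CHW / CHW = mean; batch mean of per-sample
  # normalized distances equals the overall elementwise mean of squares.
  op_mean(tape, op_square(tape, op_sub(tape, fx, fz)))
}

#' Generator adversarial loss (least squares)
#'
#' Mean squared deviation of the discriminator scores of augmented
#' supervised outputs from the generator target c = 1.
#'
#' @param tape autodiff tape
#' @param d_scores_fake_sup node of discriminator scores (any shape)
#' @return scalar node
#' @export
adversarial_loss_G <- function(tape, d_scores_fake_sup) {
  op_mean(tape, op_square(tape,
                          op_add_scalar(tape, d_scores_fake_sup, -1)))
}

#' Semisupervised score-matching loss
#'
#' Penalizes the squared difference between discriminator scores of
#' supervised and unsupervised generator outputs, anchoring the unlabeled
#' branch to the supervised restoration domain rather than to clear images.
#' Per-sample scalar scores are paired by index when the batch sizes agree;
#' otherwise the batch means are compared.  An empty unsupervised batch
#' yields 0 (supervised-only fallback).
#'
#' @param tape autodiff tape
#' @param d_scores_fake_sup score-map node for supervised outputs, dims
#'   (h, w, 1, n_s), or `NULL`
#' @param d_scores_fake_unsup score-map node for unsupervised outputs, or
#'   `NULL` when the unsupervised bank is empty
#' @return scalar node
#' @export
unsupervised_loss <- function(tape, d_scores_fake_sup,
                              d_scores_fake_unsup) {
  if (is.null(d_scores_fake_unsup)) return(op_const(tape, 0))
  ss <- op_sample_means(tape, d_scores_fake_sup)
  su <- op_sample_means(tape, d_scores_fake_unsup)
  if (length(ss$value) != length(su$value)) {
    ss <- op_mean(tape, ss)
    su <- op_mean(tape, su)
  }
  op_mean(tape, op_square(tape, op_sub(tape, ss, su)))
}

#' Weighted total generator loss
#'
#' `L_c + lambda_adv L_adv + lambda_us L_us + lambda_p L_p`.
#'
#' @param tape autodiff tape
#' @param lc,ladv,lus,lp scalar loss nodes
#' @param weights a [loss_weights()]
#' @return scalar node
#' @export
total_G_loss <- function(tape, lc, ladv, lus, lp, weights = loss_weights()) {
  comps <- c(content = lc$value, adversarial = ladv$value,
             unsupervised = lus$value, perceptual = lp$value)
  bad <- names(comps)[!is.finite(comps)]
  if (length(bad) > 0) {
    stop("non-finite loss component: ", paste(bad, collapse = ", "))
  }
  out <- op_add(tape, lc, op_scale(tape, ladv, weights$lambda_adv))
  out <- op_add(tape, out, op_scale(tape, lus, weights$lambda_us))
  op_add(tape, out, op_scale(tape, lp, weights$lambda_p))
}

#' Discriminator least-squares loss
#'
#' `1/2 E[(D(T(x)) - 1)^2] + 1/2 E[D(T(zhat_s))^2]`.  Fake scores must come
#' from detached generator outputs.
#'
#' @param tape autodiff tape
#' @param d_scores_real_aug,d_scores_fake_sup_aug score nodes
#' @return scalar node
#' @export
d_loss <- function(tape, d_scores_real_aug, d_scores_fake_sup_aug) {
  lr <- op_mean(tape, op_square(tape,
                                op_add_scalar(tape, d_scores_real_aug, -1)))
  lf <- op_mean(tape, op_square(tape, d_scores_fake_sup_aug))
  op_add(tape, op_scale(tape, lr, 0.5), op_scale(tape, lf, 0.5))
}

# ---------------------------------------------------------------------------
# Feature backbone contract: a fixed, non-trained mapping image -> feature
# block.  The default is a small frozen convolution stack with weights drawn
# from a fixed seed, so perceptual training runs fully offline and
# deterministically.  Any object with the same contract (a `fwd(tape, x)`
# returning a feature node, constant across calls) can be plugged in.
# ---------------------------------------------------------------------------

#' Frozen convolutional feature backbone
#'
#' Three 3x3 convolution + ReLU stages (the second and third with stride 2),
#' with He-initialized weights drawn from a fixed seed and never updated.
#' Serves as the perceptual feature extractor for [perceptual_loss()].
#'
#' @param channels channel widths of the three stages
#' @param seed seed for the frozen weights
#' @return backbone list with `fwd(tape, x)` and `params`
#' @export
feature_backbone <- function(channels = c(8L, 16L, 16L), seed = 774001L) {
  stopifnot(length(channels) == 3L)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  convs <- list(nn_conv("fb1", 1L, channels[1]),
                nn_conv("fb2", channels[1], channels[2], stride = 2L),
                nn_conv("fb3", channels[2], channels[3], stride = 2L))
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv) else
    rm(".Random.seed", envir = .GlobalEnv)
  list(
    convs = convs,
    params = collect_params(convs),
    frozen = TRUE,
    fwd = function(tape, x) {
      h <- x
      for (cv in convs) h <- op_relu(tape, cv$fwd(tape, h))
      # detach parameters: gradients may flow to the *image*, never to the
      # frozen weights -- enforced by wrapping params in a no-accumulate view
      h
    }
  )
}

#' Identity feature backbone (features are the image itself)
#'
#' Useful for analytic checks of the perceptual-loss arithmetic.
#' @return backbone list with `fwd(tape, x)`
#' @export
identity_backbone <- function() {
  list(params = list(), frozen = TRUE,
       fwd = function(tape, x) x)
}
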