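# Composite adversarial segmentation objective: a smoothed negative soft-Dice
# term driving overlap with the ground truth, plus a multi-scale feature
# mean-absolute-error (MAE) term computed on the discriminator's hierarchical
# feature maps. The generator minimises the weighted sum; the discriminator
# maximises the MAE component (its minimised loss is the negation), making
# the pair exactly zero-sum on the shared component.

#' Loss weights for the composite objective
#'
#' @param lam weight on the Dice term (lambda).
#' @param delta weight on the multi-scale feature MAE term.
#' @param eps Dice smoothing constant keeping the denominator positive; also
#'   fixes the empty/empty limit at a perfect score.
#' @return a `loss_weights` list.
#' @export
loss_weights <- function(lam = 1, delta = 1, eps = 1) {
  stopifnot(lam >= 0, delta >= 0, eps > 0)
  structure(list(lam = lam, delta = delta, eps = eps), class = "loss_weights")
}

#' Smoothed negative soft-Dice term for one prediction/truth pair
#'
#' Returns `-(2 * sum(pred * truth) + eps) / (sum(pred) + sum(truth) + eps)`,
#' a value in \[-1, 0\] that the generator minimises. With `pred == truth`
#' (including the all-empty case, where the eps terms dominate) the value is
#' exactly -1.
#'
#' @param pred soft prediction, values in \[0, 1\]; matrix or array.
#' @param truth binary mask of the same shape.
#' @param eps smoothing constant, > 0.
#' @return a scalar in \[-1, 0\].
#' @export
dice_term <- function(pred, truth, eps = 1) {
  if (!identical(dim(pred), dim(truth))) {
    abort("pred and truth must have identical dimensions")
  }
  stopifnot(eps > 0)
  -(2 * sum(pred * truth) + eps) / (sum(pred) + sum(truth) + eps)
}

# gradient of dice_term with respect to pred
dice_term_grad <- function(pred, truth, eps = 1) {
  P <- sum(pred); TT <- sum(truth); I <- sum(pred * truth)
  den <- P + TT + eps
  -(2 * truth * den - (2 * I + eps)) / den^2
}

#' Multi-scale feature mean-absolute-error term
#'
#' Mean absolute difference between two feature pyramids (ordered per-layer
#' discriminator feature maps on the real and generated pair), averaged
#' within each level and then across levels so deep small maps and shallow
#' large maps contribute equally.
#'
#' @param feats_real,feats_fake lists of equally shaped arrays.
#' @return a non-negative scalar; 0 iff the pyramids are identical.
#' @export
mae_term <- function(feats_real, feats_fake) {
  if (length(feats_real) != length(feats_fake)) {
    abort("feature pyramids must have the same number of levels")
  }
  lv <- purrr::map2_dbl(feats_real, feats_fake, function(r, f) {
    if (!identical(dim(r), dim(f))) {
      abort("feature pyramid levels must have identical shapes")
    }
    mean(abs(r - f))
  })
  mean(lv)
}

# gradient of mae_term with respect to feats_fake (list of arrays)
mae_term_grad_fake <- function(feats_real, feats_fake) {
  L <- length(feats_fake)
  purrr::map2(feats_real, feats_fake, function(r, f) {
    sign(f - r) / (length(f) * L)
  })
}

#' Generator objective
#'
#' The batch objective the generator minimises:
#' `(lam / N) * sum_i dice_term_i + delta * mae_term`, where the MAE term is
#' computed over pyramids carrying the whole batch (its element-wise mean
#' equals the per-item average).
#'
#' @param pred soft predictions, `(H, W, 1, N)` array (or a single matrix).
#' @param truth matching binary masks.
#' @param feats_real,feats_fake discriminator feature pyramids on the real
#'   and generated pairs.
#' @param w a [loss_weights()].
#' @return scalar loss.
#' @export
generator_objective <- function(pred, truth, feats_real, feats_fake,
                                w = loss_weights()) {
  if (is.matrix(pred)) pred <- array(pred, c(dim(pred), 1L, 1L))
  if (is.matrix(truth)) truth <- array(truth, c(dim(truth), 1L, 1L))
  n <- dim(pred)[4]
  dice <- mean(vapply(seq_len(n), function(i) {
    dice_term(pred[, , , i, drop = FALSE], truth[, , , i, drop = FALSE], w$eps)
  }, numeric(1)))
  adv <- if (w$delta > 0 || !is.null(feats_real)) {
    mae_term(feats_real, feats_fake)
  } else 0
  w$lam * dice + w$delta * adv
}

#' Discriminator objective
#'
#' The discriminator maximises the feature MAE between real and generated
#' pairs, so its minimised loss is the negation of the delta-weighted MAE
#' term. The Dice term does not depend on the discriminator and is excluded.
#'
#' @inheritParams generator_objective
#' @return scalar loss, `<= 0`.
#' @export
discriminator_objective <- function(feats_real, feats_fake, w = loss_weights()) {
  -w$delta * mae_term(feats_real, feats_fake)
}

#' Conventional GAN objective (reference form)
#'
#' The classical minimax value `E[log D(x)] + E[log(1 - D(G(z)))]` on
#' per-item probability scores. This limiting form is documented and tested
#' for reference only; the training loop never optimises it — the composite
#' Dice + feature-MAE objective replaces it.
#'
#' @param d_real,d_fake discriminator probabilities on real and generated
#'   items, values in (0, 1).
#' @return scalar value of the minimax game.
#' @export
gan_value <- function(d_real, d_fake) {
  stopifnot(all(d_real > 0), all(d_real < 1), all(d_fake > 0), all(d_fake < 1))
  mean(log(d_real)) + mean(log(1 - d_fake))
}
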