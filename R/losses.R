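# The adaptation transform and the training losses.
#
# The adaptor converts a clean-space prediction into a noisy-space
# prediction by the law of total probability,
#   y_ada = y * p(fg|fg) + (1 - y) * p(fg|bg),
# so the noisy mask can supervise y_ada directly while the backbone keeps
# learning the clean distribution. A shortcut penalty (mean squared
# difference between raw and adapted predictions) stops the adaptor from
# absorbing all supervision and starving the backbone.

#' Adaptation transform
#'
#' Per-pixel `y_ada = pred * p_fg_given_fg + (1 - pred) * p_fg_given_bg`.
#' Affine and monotone non-decreasing in `pred` wherever
#' `p_fg_given_fg >= p_fg_given_bg`.
#'
#' @param pred Probability matrix in `[0, 1]`.
#' @param cmap A [corruption_map()].
#' @return Probability matrix of the same shape.
#' @export
adapt <- function(pred, cmap) {
  assert_same_shape(pred, cmap$p_fg_given_fg, c("pred", "cmap"))
  pred * cmap$p_fg_given_fg + (1 - pred) * cmap$p_fg_given_bg
}

loss_value <- function(total, ce = NA_real_, dice = NA_real_) {
  structure(list(total = total, ce = ce, dice = dice), class = "loss_value")
}

#' @export
print.loss_value <- function(x, ...) {
  cat(sprintf("<loss> total=%.6f  (ce=%.6f, dice=%.6f)\n",
              x$total, x$ce, x$dice))
  invisible(x)
}

as_loss_scalar <- function(x) {
  if (inherits(x, "loss_value")) x$total else as.numeric(x)
}

#' Supervised segmentation loss: cross-entropy + soft Dice
#'
#' Mean per-pixel binary cross-entropy (predictions clipped to
#' `[eps_ce, 1 - eps_ce]` before the log) plus the soft-Dice loss
#' `1 - (2 * sum(p t) + eps) / (sum(p) + sum(t) + eps)`, equally weighted.
#'
#' @param pred Probability matrix.
#' @param target Binary matrix, same shape.
#' @param eps_dice Dice smoothing constant.
#' @param eps_ce Cross-entropy clipping constant.
#' @return A `loss_value` with components `total`, `ce`, `dice`.
#' @export
seg_loss <- function(pred, target, eps_dice = 1, eps_ce = 1e-7) {
  assert_binary_mask(target)
  assert_same_shape(pred, target, c("pred", "target"))
  pc <- pmin(1 - eps_ce, pmax(eps_ce, pred))
  ce <- mean(-target * log(pc) - (1 - target) * log(1 - pc))
  num <- 2 * sum(pred * target) + eps_dice
  den <- sum(pred) + sum(target) + eps_dice
  dice <- 1 - num / den
  loss_value(ce + dice, ce = ce, dice = dice)
}

# Gradient of seg_loss with respect to `pred`; `dice_weight` scales the
# Dice component (1 = the equally weighted default of seg_loss).
seg_loss_grad <- function(pred, target, eps_dice = 1, eps_ce = 1e-7,
                          dice_weight = 1) {
  n <- length(pred)
  pc <- pmin(1 - eps_ce, pmax(eps_ce, pred))
  g_ce <- (pc - target) / (pc * (1 - pc)) / n
  # clipped pixels have zero CE gradient flow through the clip
  g_ce[pred < eps_ce | pred > 1 - eps_ce] <- 0
  num <- 2 * sum(pred * target) + eps_dice
  den <- sum(pred) + sum(target) + eps_dice
  g_dice <- -(2 * target * den - num) / den^2
  g_ce + dice_weight * g_dice
}

#' Adaptor loss: noisy labels supervise the adapted prediction
#'
#' `seg_loss(adapt(pred, cmap), noisy_target)` — the only loss in which
#' noisy masks act as direct supervision; the adaptor models the corruption
#' process from accurate to noisy labels.
#'
#' @param pred Probability matrix (backbone output).
#' @param cmap A [corruption_map()].
#' @param noisy_target Binary matrix of noisy labels.
#' @inheritParams seg_loss
#' @return A `loss_value`.
#' @export
adaptor_loss <- function(pred, cmap, noisy_target, eps_dice = 1, eps_ce = 1e-7) {
  seg_loss(adapt(pred, cmap), noisy_target, eps_dice = eps_dice,
           eps_ce = eps_ce)
}

#' Shortcut penalty
#'
#' Mean squared difference between the raw and adapted predictions. Large
#' weights drive the learned corruption map toward the identity.
#'
#' @param pred,adapted Probability matrices of equal shape.
#' @return A `loss_value` (no ce/dice components).
#' @export
shortcut_penalty <- function(pred, adapted) {
  assert_same_shape(pred, adapted, c("pred", "adapted"))
  loss_value(mean((pred - adapted)^2))
}

# Combined gradients of  L_ada + beta_reg * sigma  with respect to the
# backbone probability map and the two corruption-map channels. Returns the
# loss components as well, so the training loop evaluates everything once.
# `dice_weight` scales the Dice part of the adaptor channel: the default 0
# trains the corruption map by cross-entropy alone, which is the
# likelihood-consistent choice when the map is read as a conditional
# corruption probability (the Dice gradient on minority-class pixels is far
# stronger than the CE gradient and pushes the adapted map toward hard
# labels rather than toward the corruption rate).
adaptor_grads <- function(pred, cmap, noisy_target, beta_reg,
                          dice_weight = 0, eps_dice = 1, eps_ce = 1e-7) {
  a <- cmap$p_fg_given_fg
  b <- cmap$p_fg_given_bg
  yada <- pred * a + (1 - pred) * b
  n <- length(pred)
  parts <- seg_loss(yada, noisy_target, eps_dice, eps_ce)
  l_ada <- loss_value(parts$ce + dice_weight * parts$dice,
                      ce = parts$ce, dice = parts$dice)
  g_yada <- seg_loss_grad(yada, noisy_target, eps_dice, eps_ce,
                          dice_weight = dice_weight)
  diffp <- pred - yada
  sigma <- mean(diffp^2)
  gpred <- g_yada * (a - b) + beta_reg * 2 * diffp * (1 - (a - b)) / n
  ga <- g_yada * pred - beta_reg * 2 * diffp * pred / n
  gb <- g_yada * (1 - pred) - beta_reg * 2 * diffp * (1 - pred) / n
  list(l_ada = l_ada, sigma = sigma, gpred = gpred,
       gcmap = list(ga, gb))
}
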