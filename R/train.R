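# Training harness. Composes the total loss
#   L = L_sup(Dc) + beta_ada * (L_ada(Dn) + beta_reg * sigma)
#       + ramp * beta_semi * (L_semi(Dc) + L_semi(Dn)),
# runs the optimization loop (adaptive-moment optimizer, decoupled weight
# decay, gradient accumulation, reduce-on-plateau learning-rate decay) and
# the masked-EMA teacher updates, and exposes the result as a classed model
# object. Dataset routing: clean samples supervise the backbone directly;
# noisy samples supervise only through the adaptor — except in the naive
# baseline (beta_ada = 0), where noisy masks are deliberately treated as
# ordinary labels, which is exactly the degraded regime the noise-rate study
# measures.

#' Loss weights
#'
#' @param beta_ada Weight of the adaptor supervision.
#' @param beta_reg Weight of the shortcut penalty inside the adaptor term.
#' @param beta_semi Weight of the consistency term.
#' @param semi_ramp_frac Fraction of total epochs over which the
#'   consistency weight ramps linearly from ~0 to full (prevents early,
#'   unreliable pseudo-labels from dominating).
#' @param ada_dice_weight Weight of the Dice part inside the adaptor
#'   channel. The default 0 trains the corruption map by cross-entropy
#'   alone: CE is minimized exactly at the conditional corruption
#'   probability, whereas the Dice gradient drives the adapted map toward
#'   hard labels and destroys the map's probabilistic reading.
#' @param semi_dice_weight Weight of the Dice part inside the consistency
#'   channel. The default 0 uses bounded cross-entropy consistency: the
#'   soft-Dice loss against an *empty* pseudo-label is a sharp attractor at
#'   the all-background state (its gradient grows as predictions shrink)
#'   and can saturate the network irrecoverably before the teachers become
#'   informative. The supervised loss always keeps CE + Dice.
#' @export
loss_weights <- function(beta_ada = 1, beta_reg = 0.1, beta_semi = 1,
                         semi_ramp_frac = 0.3, ada_dice_weight = 0,
                         semi_dice_weight = 0) {
  if (any(c(beta_ada, beta_reg, beta_semi, ada_dice_weight,
            semi_dice_weight) < 0)) {
    stop("loss weights must be non-negative", call. = FALSE)
  }
  structure(list(beta_ada = beta_ada, beta_reg = beta_reg,
                 beta_semi = beta_semi, semi_ramp_frac = semi_ramp_frac,
                 ada_dice_weight = ada_dice_weight,
                 semi_dice_weight = semi_dice_weight),
            class = "loss_weights")
}

# Consistency ramp in [0, 1], non-decreasing in epoch: the classic sigmoid
# ramp-up exp(-5 (1 - t)^2) with t = epoch / ramp_epochs. Near-zero for the
# first epochs so supervision establishes the foreground before the
# (initially uninformative) teachers weigh in; without this the consistency
# term can lock the model into an all-background fixed point.
ramp_multiplier <- function(epoch, epochs, frac) {
  if (frac <= 0) return(1)
  k <- max(1, ceiling(frac * epochs))
  t <- min(1, epoch / k)
  exp(-5 * (1 - t)^2)
}

#' Training configuration
#'
#' Optimizer defaults follow the reference regime (initial learning rate
#' 0.001, weight decay 0.0001, gradients accumulated every 2 batches,
#' plateau-triggered decay by a factor of 10); batch size and epoch count
#' default to desk scale.
#'
#' @param lr Initial learning rate.
#' @param weight_decay Decoupled weight decay.
#' @param accum Gradient-accumulation interval (batches per optimizer step).
#' @param batch_size Samples per batch.
#' @param plateau_factor Learning-rate division factor on plateau.
#' @param patience Epochs without validation improvement before decay.
#' @param epochs Training epochs.
#' @param seed Seed driving shuffling, augmentation, dropout and teacher
#'   masks (each on an independent substream).
#' @export
training_config <- function(lr = 1e-3, weight_decay = 1e-4, accum = 2L,
                            batch_size = 8L, plateau_factor = 10,
                            patience = 5L, epochs = 30L, seed = 1L) {
  if (lr <= 0 || plateau_factor <= 1) {
    stop("`lr` must be positive and `plateau_factor` > 1", call. = FALSE)
  }
  structure(list(lr = lr, weight_decay = weight_decay,
                 accum = as.integer(accum), batch_size = as.integer(batch_size),
                 plateau_factor = plateau_factor, patience = as.integer(patience),
                 epochs = as.integer(epochs), seed = as.integer(seed)),
            class = "training_config")
}

#' Total training loss
#'
#' `L = l_sup + beta_ada * (l_ada + beta_reg * sigma) +
#'  ramp(epoch) * beta_semi * (l_semi_clean + l_semi_noisy)`.
#'
#' @param l_sup,l_ada,sigma,l_semi_clean,l_semi_noisy Loss components
#'   (`loss_value` objects or numerics).
#' @param w A [loss_weights()].
#' @param epoch,epochs Current epoch and total epochs (drive the ramp).
#' @return The scalar total loss.
#' @export
total_loss <- function(l_sup, l_ada = 0, sigma = 0, l_semi_clean = 0,
                       l_semi_noisy = 0, w = loss_weights(), epoch = 1,
                       epochs = 1) {
  comps <- c(l_sup = as_loss_scalar(l_sup), l_ada = as_loss_scalar(l_ada),
             sigma = as_loss_scalar(sigma),
             l_semi_clean = as_loss_scalar(l_semi_clean),
             l_semi_noisy = as_loss_scalar(l_semi_noisy))
  bad <- !is.finite(comps)
  if (any(bad)) {
    stop(sprintf("non-finite loss component(s): %s",
                 paste(names(comps)[bad], collapse = ", ")), call. = FALSE)
  }
  r <- ramp_multiplier(epoch, epochs, w$semi_ramp_frac)
  unname(comps["l_sup"] +
           w$beta_ada * (comps["l_ada"] + w$beta_reg * comps["sigma"]) +
           r * w$beta_semi * (comps["l_semi_clean"] + comps["l_semi_noisy"]))
}

# Adam with decoupled weight decay on a flat parameter vector.
adam_step <- function(state, grad, lr, weight_decay,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  state$par <- state$par - lr * (mhat / (sqrt(vhat) + eps) +
                                   weight_decay * state$par)
  state
}

grad_flat_add <- function(acc, grads) {
  acc + par_flatten(grads)
}

#' Fit a noise-robust segmentation model
#'
#' Trains the backbone + adaptor on a mixed clean/noisy dataset. Per batch:
#' clean samples contribute the supervised loss on the weak view; noisy
#' samples contribute the adaptor loss and shortcut penalty (their masks
#' never supervise the backbone directly unless `beta_ada = 0`); when
#' `beta_semi > 0` every sample also contributes a consistency loss between
#' the student's strong view and a two-threshold pseudo-label computed from
#' the teacher ensemble on the weak view. Teachers follow the student by
#' masked EMA after every optimizer step.
#'
#' @param manifest A `dataset_manifest` (training rows), or a list of
#'   [image_sample()]s.
#' @param val Optional validation manifest / sample list with clean masks.
#' @param backbone A [unet_config()].
#' @param weights A [loss_weights()].
#' @param control A [training_config()].
#' @param perturb_spec A [perturbation_spec()] (weak + strong settings).
#' @param teachers A [teacher_ensemble()] configuration.
#' @param pseudo A [pseudo_label_config()].
#' @param semi_ignore_labels If `TRUE`, the pseudo-label rule ignores the
#'   available label (drops the second clause), treating all data as
#'   unlabeled for the consistency term.
#' @param verbose Print a line per epoch.
#' @return An object of class `mpvt_fit`.
#' @export
mpvt <- function(manifest, val = NULL, backbone = unet_config(),
                 weights = loss_weights(), control = training_config(),
                 perturb_spec = perturbation_spec(),
                 teachers = teacher_ensemble(),
                 pseudo = pseudo_label_config(),
                 semi_ignore_labels = FALSE, verbose = FALSE) {
  samples <- if (inherits(manifest, "dataset_manifest")) load_samples(manifest)
             else manifest
  val_samples <- if (is.null(val)) list()
                 else if (inherits(val, "dataset_manifest")) load_samples(val)
                 else val
  n <- length(samples)
  if (n < 1) stop("no training samples", call. = FALSE)
  is_noisy <- vapply(samples, function(s) s$purity == "noisy", logical(1))
  use_adaptor <- weights$beta_ada > 0
  use_semi <- weights$beta_semi > 0
  n_sup <- sum(!is_noisy) + if (!use_adaptor) sum(is_noisy) else 0
  if (n_sup == 0) {
    stop("supervised loss has no contributing samples: need clean data ",
         "(or beta_ada = 0 so noisy masks supervise directly)", call. = FALSE)
  }

  model <- unet_init(backbone, seed = control$seed)
  template <- model$params
  opt <- list(par = par_flatten(template), m = 0, v = 0, t = 0)
  np <- length(opt$par)
  opt$m <- numeric(np); opt$v <- numeric(np)

  teach <- lapply(seq_len(teachers$K), function(k) opt$par)
  activation_epochs <- pmax(1, ceiling(teachers$activation_fracs *
                                         control$epochs))
  activation_epochs[teachers$activation_fracs == 0] <- 1

  lr <- control$lr
  best_val <- Inf
  stall <- 0
  log <- NULL
  feature_pert <- if (perturb_spec$feature_rate > 0)
    list(rate = perturb_spec$feature_rate) else NULL

  for (epoch in seq_len(control$epochs)) {
    order_idx <- with_seed(mix_seed(control$seed, 3L, epoch), sample(n))
    model$params <- par_unflatten(opt$par, template)
    sums <- c(sup = 0, ada = 0, sigma = 0, semi = 0)
    counts <- c(sup = 0, ada = 0, semi = 0)
    gacc <- numeric(np)
    acc_count <- 0
    step_id <- 0
    chunk <- control$batch_size * control$accum

    for (pos in seq_along(order_idx)) {
      idx <- order_idx[pos]
      s <- samples[[idx]]
      sseed <- mix_seed(control$seed, 5L, epoch, idx)
      pw <- perturb(s$image, s$mask, perturb_spec, stage = "weak",
                    seed = sseed)
      fw <- unet_forward(model, pw$image, stochastic = FALSE,
                         want_cache = TRUE)
      gprob <- matrix(0, nrow(pw$image), ncol(pw$image))
      gcmap <- NULL
      if (!is_noisy[idx] || !use_adaptor) {
        l <- seg_loss(fw$prob, pw$mask)
        gprob <- gprob + seg_loss_grad(fw$prob, pw$mask)
        sums["sup"] <- sums["sup"] + l$total
        counts["sup"] <- counts["sup"] + 1
      } else {
        ag <- adaptor_grads(fw$prob, fw$cmap, pw$mask, weights$beta_reg,
                            dice_weight = weights$ada_dice_weight)
        gprob <- gprob + weights$beta_ada * ag$gpred
        gcmap <- list(weights$beta_ada * ag$gcmap[[1]],
                      weights$beta_ada * ag$gcmap[[2]])
        sums["ada"] <- sums["ada"] + ag$l_ada$total
        sums["sigma"] <- sums["sigma"] + ag$sigma
        counts["ada"] <- counts["ada"] + 1
      }
      grads <- unet_backward(model, fw$cache, gprob, gcmap)
      gacc <- gacc + par_flatten(grads)

      if (use_semi) {
        active <- which(activation_epochs <= epoch)
        if (length(active) == 0) active <- 1L
        tpred <- ensemble_predict(teach[active], model, pw$image)
        avail <- if (semi_ignore_labels)
          matrix(0, nrow(pw$mask), ncol(pw$mask)) else pw$mask
        plab <- make_pseudo_label(tpred, avail, pseudo)
        ps <- perturb(s$image, s$mask, perturb_spec, stage = "strong",
                      seed = sseed)
        fs <- unet_forward(model, ps$image, stochastic = TRUE,
                           feature_perturbation = feature_pert,
                           seed = mix_seed(sseed, 9L), want_cache = TRUE)
        parts <- semi_loss(fs$prob, plab)
        lsemi <- loss_value(parts$ce + weights$semi_dice_weight * parts$dice,
                            ce = parts$ce, dice = parts$dice)
        r <- ramp_multiplier(epoch, control$epochs, weights$semi_ramp_frac)
        gsemi <- r * weights$beta_semi *
          seg_loss_grad(fs$prob, plab,
                        dice_weight = weights$semi_dice_weight)
        grads_s <- unet_backward(model, fs$cache, gsemi, NULL)
        gacc <- gacc + par_flatten(grads_s)
        sums["semi"] <- sums["semi"] + lsemi$total
        counts["semi"] <- counts["semi"] + 1
      }
      acc_count <- acc_count + 1

      if (acc_count == chunk || pos == length(order_idx)) {
        step_id <- step_id + 1
        opt <- adam_step(opt, gacc / acc_count, lr, control$weight_decay)
        model$params <- par_unflatten(opt$par, template)
        for (k in seq_len(teachers$K)) {
          if (epoch >= activation_epochs[k]) {
            teach[[k]] <- masked_ema_update(
              teach[[k]], opt$par, teachers$ema_decay,
              teachers$update_mask_rate,
              seed = mix_seed(control$seed, 7L, epoch, step_id, k))
          }
        }
        gacc <- numeric(np)
        acc_count <- 0
      }
    }

    mean_or_0 <- function(s, c) if (c > 0) s / c else 0
    l_sup <- mean_or_0(sums["sup"], counts["sup"])
    l_ada <- mean_or_0(sums["ada"], counts["ada"])
    sig <- mean_or_0(sums["sigma"], counts["ada"])
    l_semi <- mean_or_0(sums["semi"], counts["semi"])
    train_total <- total_loss(l_sup, l_ada, sig, l_semi, 0, weights,
                              epoch, control$epochs)

    val_loss <- NA_real_; val_dsc <- NA_real_
    if (length(val_samples) > 0) {
      vl <- 0; vd <- 0
      for (vs in val_samples) {
        pr <- unet_forward(model, vs$image, stochastic = FALSE)$prob
        vl <- vl + seg_loss(pr, vs$mask)$total
        vd <- vd + segmentation_scores((pr >= 0.5) * 1, vs$mask)[["dsc"]]
      }
      val_loss <- vl / length(val_samples)
      val_dsc <- vd / length(val_samples)
    }

    monitor <- if (!is.na(val_loss)) val_loss else train_total
    if (monitor < best_val - 1e-8) {
      best_val <- monitor
      stall <- 0
    } else {
      stall <- stall + 1
      if (stall > control$patience) {
        lr <- lr / control$plateau_factor
        stall <- 0
      }
    }

    log <- rbind(log, data.frame(epoch = epoch, lr = lr, loss_sup = l_sup,
                                 loss_ada = l_ada, sigma = sig,
                                 loss_semi = l_semi, loss_total = train_total,
                                 val_loss = val_loss, val_dsc = val_dsc))
    if (verbose) {
      cat(sprintf("epoch %3d  loss %.4f  (sup %.4f ada %.4f semi %.4f)  val_dsc %s\n",
                  epoch, train_total, l_sup, l_ada, l_semi,
                  ifelse(is.na(val_dsc), "-", sprintf("%.1f", val_dsc))))
    }
  }

  model$params <- par_unflatten(opt$par, template)
  structure(list(model = model, teachers = teach,
                 teacher_config = teachers, weights = weights,
                 control = control, perturb_spec = perturb_spec,
                 pseudo = pseudo, log = log,
                 n_clean = sum(!is_noisy), n_noisy = sum(is_noisy)),
            class = "mpvt_fit")
}

#' @export
print.mpvt_fit <- function(x, ...) {
  cat("Noise-robust segmentation fit\n")
  cat(sprintf("  backbone: depth %d, base width %d; %d parameters\n",
              x$model$config$depth, x$model$config$base_width,
              length(par_flatten(x$model$params))))
  cat(sprintf("  data: %d clean + %d noisy training samples\n",
              x$n_clean, x$n_noisy))
  cat(sprintf("  weights: beta_ada=%g beta_reg=%g beta_semi=%g; %d teachers\n",
              x$weights$beta_ada, x$weights$beta_reg, x$weights$beta_semi,
              x$teacher_config$K))
  last <- x$log[nrow(x$log), ]
  cat(sprintf("  final epoch %d: loss %.4f%s\n", last$epoch, last$loss_total,
              ifelse(is.na(last$val_dsc), "",
                     sprintf(", validation DSC %.1f", last$val_dsc))))
  invisible(x)
}

#' @export
summary.mpvt_fit <- function(object, ...) {
  cat("Training log (last 5 epochs):\n")
  print(utils::tail(object$log, 5), row.names = FALSE)
  invisible(object$log)
}

#' @export
plot.mpvt_fit <- function(x, ...) {
  graphics::plot(x$log$epoch, x$log$loss_total, type = "l",
                 xlab = "epoch", ylab = "loss",
                 main = "training loss", ...)
  if (any(!is.na(x$log$val_loss))) {
    graphics::lines(x$log$epoch, x$log$val_loss, lty = 2)
    graphics::legend("topright", legend = c("train", "validation"),
                     lty = c(1, 2), bty = "n")
  }
  invisible(x)
}

#' Predict segmentation maps
#'
#' @param object An `mpvt_fit`.
#' @param newdata A matrix, a list of matrices / [image_sample()]s, or a
#'   `dataset_manifest`.
#' @param type `"prob"` for probability maps, `"mask"` for thresholded
#'   binary masks.
#' @param threshold Binarization threshold for `type = "mask"`.
#' @param ... Unused.
#' @return A matrix, or a list of matrices (named by sample id when ids are
#'   known).
#' @export
predict.mpvt_fit <- function(object, newdata, type = c("prob", "mask"),
                             threshold = 0.5, ...) {
  type <- match.arg(type)
  one <- function(img) {
    pr <- unet_forward(object$model, img, stochastic = FALSE)$prob
    if (type == "mask") (pr >= threshold) * 1 else pr
  }
  if (is.matrix(newdata)) return(one(newdata))
  samples <- if (inherits(newdata, "dataset_manifest")) load_samples(newdata)
             else newdata
  out <- lapply(samples, function(s) {
    one(if (inherits(s, "image_sample")) s$image else s)
  })
  nm <- vapply(samples, function(s)
    if (inherits(s, "image_sample")) s$id else NA_character_, character(1))
  if (!anyNA(nm)) names(out) <- nm
  out
}

#' Recovered corruption rates
#'
#' Reads the trained adaptor's corruption map on the noisy-subset images
#' (deterministic forward pass) and averages it over ground-truth classes:
#' `rho01_hat` = mean `p_fg_given_bg` over true-background pixels,
#' `rho10_hat` = mean `1 - p_fg_given_fg` over true-foreground pixels. When
#' the noisy masks were produced by constant-rate flips these estimates
#' should approach the injected rates.
#'
#' @param fit An `mpvt_fit`.
#' @param samples Noisy [image_sample()]s whose `meta$truth` holds the
#'   accurate mask (as produced by [generate_dataset()] sidecars).
#' @return Named vector `c(rho01_hat, rho10_hat)`.
#' @export
recovered_corruption_rates <- function(fit, samples) {
  r01 <- numeric(0); r10 <- numeric(0)
  for (s in samples) {
    truth <- s$meta$truth
    if (is.null(truth)) stop("samples need meta$truth", call. = FALSE)
    fw <- unet_forward(fit$model, s$image, stochastic = FALSE)
    r01 <- c(r01, mean(fw$cmap$p_fg_given_bg[truth == 0]))
    r10 <- c(r10, 1 - mean(fw$cmap$p_fg_given_fg[truth == 1]))
  }
  c(rho01_hat = mean(r01), rho10_hat = mean(r10))
}

#' Evaluate a fit against ground truth
#'
#' Scores thresholded predictions against the accurate (`_truth` sidecar)
#' masks of a manifest.
#'
#' @param fit An `mpvt_fit`.
#' @param manifest A `dataset_manifest` (or list of samples whose
#'   `meta$truth` is set).
#' @param threshold Binarization threshold.
#' @return A [score_table()].
#' @export
evaluate_fit <- function(fit, manifest, threshold = 0.5) {
  samples <- if (inherits(manifest, "dataset_manifest")) load_samples(manifest)
             else manifest
  preds <- lapply(samples, function(s)
    (unet_forward(fit$model, s$image, stochastic = FALSE)$prob >= threshold) * 1)
  truths <- lapply(samples, function(s) s$meta$truth %||% s$mask)
  score_table(preds, truths, ids = vapply(samples, `[[`, character(1), "id"))
}
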