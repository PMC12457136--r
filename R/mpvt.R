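# Multi-stage perturbations and variable teachers.
#
# Consistency training perturbs each sample at three stages: weak geometric
# transforms (shared pixel-for-pixel between image and mask, and between the
# weak and strong views so pseudo-labels stay aligned), strong photometric
# extras applied to the image only, and multiplicative dropout on the
# bottleneck features. Pseudo-labels come from an ensemble of mean teachers
# whose EMA updates are stochastically masked per parameter and staggered
# across training stages.

#' Perturbation settings
#'
#' @param hflip_p,vflip_p Flip probabilities for the weak geometric stage.
#' @param max_translate Maximum absolute translation, pixels (integer draw).
#' @param max_rotate Maximum absolute rotation, degrees.
#' @param jitter Additive intensity shift drawn from `[-jitter, jitter]`
#'   (strong stage only).
#' @param gamma_range Gamma-correction exponent range (strong only).
#' @param blur_sigma_range Gaussian blur sigma range (strong only).
#' @param noise_sd Additive Gaussian noise sd (strong only).
#' @param cutout_n,cutout_size Number and side length of zeroed squares
#'   (strong only).
#' @param feature_rate Multiplicative-dropout rate on bottleneck features
#'   (the feature-level perturbation stage).
#' @return An object of class `perturbation_spec`.
#' @export
perturbation_spec <- function(hflip_p = 0.5, vflip_p = 0.2, max_translate = 4,
                              max_rotate = 10, jitter = 0.08,
                              gamma_range = c(0.8, 1.25),
                              blur_sigma_range = c(0, 0.8), noise_sd = 0.02,
                              cutout_n = 1, cutout_size = 8,
                              feature_rate = 0.3) {
  probs <- c(hflip_p, vflip_p)
  if (any(probs < 0) || any(probs > 1)) {
    stop("flip probabilities must lie in [0, 1]", call. = FALSE)
  }
  structure(list(hflip_p = hflip_p, vflip_p = vflip_p,
                 max_translate = max_translate, max_rotate = max_rotate,
                 jitter = jitter, gamma_range = gamma_range,
                 blur_sigma_range = blur_sigma_range, noise_sd = noise_sd,
                 cutout_n = cutout_n, cutout_size = cutout_size,
                 feature_rate = feature_rate),
            class = "perturbation_spec")
}

#' @rdname perturbation_spec
#' @export
identity_perturbation_spec <- function() {
  perturbation_spec(hflip_p = 0, vflip_p = 0, max_translate = 0,
                    max_rotate = 0, jitter = 0, gamma_range = c(1, 1),
                    blur_sigma_range = c(0, 0), noise_sd = 0, cutout_n = 0,
                    cutout_size = 0, feature_rate = 0)
}

# Draw the geometric part of a transform. The same seed always yields the
# same record, which is how the strong view shares the weak view's geometry.
draw_transform <- function(spec, seed) {
  with_seed(mix_seed(seed, 81L), {
    list(hflip = runif(1) < spec$hflip_p,
         vflip = runif(1) < spec$vflip_p,
         angle = if (spec$max_rotate > 0) runif(1, -spec$max_rotate,
                                                spec$max_rotate) else 0,
         dy = if (spec$max_translate > 0)
           sample(-spec$max_translate:spec$max_translate, 1) else 0L,
         dx = if (spec$max_translate > 0)
           sample(-spec$max_translate:spec$max_translate, 1) else 0L)
  })
}

#' Re-apply the geometric part of a transform record to any grid
#'
#' @param grid Numeric matrix.
#' @param record A transform record from [perturb()].
#' @param interp `"nearest"` (exact for binary masks) or `"bilinear"`.
#' @param fill Fill value outside the source grid.
#' @export
apply_geometric <- function(grid, record, interp = c("nearest", "bilinear"),
                            fill = 0) {
  interp <- match.arg(interp)
  if (!record$hflip && !record$vflip && record$angle == 0 &&
      record$dy == 0 && record$dx == 0) {
    return(grid)
  }
  cpp_warp_rigid(grid, record$hflip, record$vflip, record$angle,
                 as.integer(record$dy), as.integer(record$dx),
                 interp == "bilinear", fill)
}

apply_photometric <- function(image, spec, seed) {
  with_seed(mix_seed(seed, 83L), {
    img <- image
    if (spec$jitter > 0) img <- img + runif(1, -spec$jitter, spec$jitter)
    img <- clamp01(img)
    if (!all(spec$gamma_range == 1)) {
      img <- img^runif(1, spec$gamma_range[1], spec$gamma_range[2])
    }
    if (spec$blur_sigma_range[2] > 0) {
      sg <- runif(1, spec$blur_sigma_range[1], spec$blur_sigma_range[2])
      if (sg > 0.05) img <- matrix(EBImage::gblur(img, sigma = sg),
                                   nrow(img), ncol(img))
    }
    if (spec$noise_sd > 0) {
      img <- img + matrix(rnorm(length(img), 0, spec$noise_sd),
                          nrow(img), ncol(img))
    }
    if (spec$cutout_n > 0 && spec$cutout_size > 0) {
      for (k in seq_len(spec$cutout_n)) {
        i0 <- sample.int(max(1, nrow(img) - spec$cutout_size + 1), 1)
        j0 <- sample.int(max(1, ncol(img) - spec$cutout_size + 1), 1)
        img[i0:min(nrow(img), i0 + spec$cutout_size - 1),
            j0:min(ncol(img), j0 + spec$cutout_size - 1)] <- 0
      }
    }
    clamp01(img)
  })
}

#' Perturb an image (and optionally its mask)
#'
#' The weak stage applies a seeded geometric transform identically to image
#' and mask. The strong stage applies the *same* geometric transform (same
#' seed, same record) plus photometric-only extras to the image; the mask is
#' only transformed geometrically, so weak and strong views of a sample are
#' pixel-aligned.
#'
#' @param image Intensity matrix.
#' @param mask Optional binary matrix.
#' @param spec A [perturbation_spec()].
#' @param stage `"weak"` or `"strong"`.
#' @param seed Integer seed; the geometric draw depends only on
#'   `(spec, seed)`, not on the stage.
#' @return `list(image, mask, record)`.
#' @export
perturb <- function(image, mask = NULL, spec, stage = c("weak", "strong"),
                    seed = 1L) {
  stage <- match.arg(stage)
  record <- draw_transform(spec, seed)
  img <- apply_geometric(image, record, interp = "bilinear")
  msk <- if (!is.null(mask)) apply_geometric(mask, record, interp = "nearest")
         else NULL
  if (stage == "strong") {
    img <- apply_photometric(img, spec, seed)
  }
  list(image = img, mask = msk, record = record)
}

# ---- variable teachers -----------------------------------------------------

#' Teacher-ensemble configuration
#'
#' `K` mean teachers whose parameters track the student by a per-parameter
#' stochastically *masked* EMA (each scalar updates with probability
#' `update_mask_rate` per step), and whose updates start at staggered
#' activation epochs so the ensemble mixes teachers from different stages of
#' training. Before activation a teacher stays frozen at its initialization
#' snapshot.
#'
#' @param K Number of teachers (>= 1).
#' @param ema_decay EMA decay `alpha` in `[0, 1)`.
#' @param update_mask_rate Per-parameter update probability `m` in `[0, 1]`.
#' @param activation_fracs Fractions of total epochs at which each teacher
#'   starts updating (recycled to length `K`).
#' @return An object of class `teacher_ensemble_config`.
#' @export
teacher_ensemble <- function(K = 3L, ema_decay = 0.95, update_mask_rate = 0.5,
                             activation_fracs = c(0, 1 / 3, 2 / 3)) {
  if (K < 1) stop("`K` must be >= 1", call. = FALSE)
  if (ema_decay < 0 || ema_decay >= 1) {
    stop("`ema_decay` must lie in [0, 1)", call. = FALSE)
  }
  if (update_mask_rate < 0 || update_mask_rate > 1) {
    stop("`update_mask_rate` must lie in [0, 1]", call. = FALSE)
  }
  structure(list(K = as.integer(K), ema_decay = ema_decay,
                 update_mask_rate = update_mask_rate,
                 activation_fracs = rep_len(activation_fracs, K)),
            class = "teacher_ensemble_config")
}

#' Masked EMA update of one teacher parameter vector
#'
#' Per scalar parameter, with probability `update_mask_rate` the usual EMA
#' update `t <- alpha * t + (1 - alpha) * s` is applied; otherwise the
#' parameter is left unchanged.
#'
#' @param teacher,student Flat numeric parameter vectors of equal length.
#' @param ema_decay,update_mask_rate As in [teacher_ensemble()].
#' @param seed Integer seed for the update mask.
#' @return Updated teacher vector.
#' @export
masked_ema_update <- function(teacher, student, ema_decay, update_mask_rate,
                              seed = 1L) {
  if (length(teacher) != length(student)) {
    stop("teacher and student parameter sets are not congruent", call. = FALSE)
  }
  if (update_mask_rate == 0) return(teacher)
  upd <- if (update_mask_rate >= 1) {
    rep(TRUE, length(teacher))
  } else {
    with_seed(mix_seed(seed, 91L),
              runif(length(teacher)) < update_mask_rate)
  }
  teacher[upd] <- ema_decay * teacher[upd] + (1 - ema_decay) * student[upd]
  teacher
}

#' Mean prediction of a teacher ensemble
#'
#' @param teachers List of flat teacher parameter vectors (the active
#'   ensemble; must be non-empty).
#' @param model A `unet_model` whose `params` provide the array template.
#' @param image Intensity matrix.
#' @return A foreground probability matrix (mean of the teachers'
#'   deterministic forward passes).
#' @export
ensemble_predict <- function(teachers, model, image) {
  if (length(teachers) == 0) stop("empty teacher ensemble", call. = FALSE)
  acc <- 0
  for (tv in teachers) {
    m <- model
    m$params <- par_unflatten(tv, model$params)
    acc <- acc + unet_forward(m, image, stochastic = FALSE)$prob
  }
  acc / length(teachers)
}

# ---- pseudo-labels ---------------------------------------------------------

#' Two-threshold pseudo-label configuration
#'
#' `tau1` promotes any pixel the teacher is confident about; `tau2` keeps a
#' labelled-foreground pixel unless the teacher confidently disagrees. The
#' default `tau2 = 0.4` sits below an untrained teacher's output level so
#' the label clause can bootstrap pseudo-labels from the supervision signal;
#' with a high `tau2` early pseudo-labels are empty and the consistency term
#' can collapse the model to all-background.
#'
#' @param tau1 Upper confidence threshold.
#' @param tau2 Lower confidence threshold (`tau2 <= tau1`).
#' @export
pseudo_label_config <- function(tau1 = 0.9, tau2 = 0.4) {
  if (!(tau2 <= tau1 && tau1 <= 1 && tau2 >= 0)) {
    stop("need 0 <= tau2 <= tau1 <= 1", call. = FALSE)
  }
  structure(list(tau1 = tau1, tau2 = tau2), class = "pseudo_label_config")
}

#' Two-threshold pseudo-label rule
#'
#' A pixel is pseudo-foreground iff the teacher confidence reaches `tau1`,
#' or it reaches the lower threshold `tau2` while the available (possibly
#' noisy) label already marks it foreground. Everything else is
#' pseudo-background; there is no abstain state.
#'
#' @param teacher_pred Probability matrix from [ensemble_predict()].
#' @param available_label Binary matrix: the sample's label as given (noisy
#'   for the noisy subset, clean otherwise), geometrically aligned with
#'   `teacher_pred`.
#' @param cfg A [pseudo_label_config()].
#' @return Binary matrix.
#' @export
make_pseudo_label <- function(teacher_pred, available_label, cfg) {
  assert_same_shape(teacher_pred, available_label,
                    c("teacher_pred", "available_label"))
  assert_binary_mask(available_label)
  out <- (teacher_pred >= cfg$tau1) |
    (teacher_pred >= cfg$tau2 & available_label == 1)
  matrix(as.numeric(out), nrow(teacher_pred), ncol(teacher_pred))
}

#' Semi-supervised consistency loss
#'
#' `seg_loss` between the student's strong-view prediction and the
#' weak-view pseudo-label (aligned via the shared geometric record).
#'
#' @param student_pred_strong Probability matrix.
#' @param pseudo Binary pseudo-label matrix.
#' @inheritParams seg_loss
#' @return A `loss_value`.
#' @export
semi_loss <- function(student_pred_strong, pseudo, eps_dice = 1,
                      eps_ce = 1e-7) {
  seg_loss(student_pred_strong, pseudo, eps_dice = eps_dice, eps_ce = eps_ce)
}
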