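test_that("total loss composes the weighted components", {
  w0 <- loss_weights(beta_ada = 0, beta_reg = 0, beta_semi = 0)
  expect_equal(total_loss(1.7, 2, 3, 4, 5, w0), 1.7)

  # consistency disabled: reduces to supervised + adaptor form
  w_ns <- loss_weights(beta_ada = 1, beta_reg = 0.1, beta_semi = 0)
  expect_equal(total_loss(1, 2, 0.5, 9, 9, w_ns), 1 + (2 + 0.1 * 0.5))

  w <- loss_weights(beta_ada = 1, beta_reg = 0.1, beta_semi = 0.5,
                    semi_ramp_frac = 0)   # ramp pinned at 1
  expect_equal(total_loss(1, 2, 0.5, 0.3, 0.3, w, epoch = 1, epochs = 1),
               1 + (2 + 0.05) + 0.5 * 0.6)  # 3.35

  expect_error(total_loss(Inf, 0, 0, 0, 0, w0), "l_sup")
  expect_error(total_loss(1, NaN, 0, 0, 0, w_ns), "l_ada")
})

test_that("total loss is linear in every component", {
  oracle <- function(ls, la, sg, sc, sn, ba, br, bs, r) {
    ls + ba * (la + br * sg) + r * bs * (sc + sn)
  }
  for (sd in 1:20) {
    v <- noisyseg:::with_seed(sd, runif(8))
    w <- loss_weights(beta_ada = v[6], beta_reg = v[7], beta_semi = v[8],
                      semi_ramp_frac = 0)
    expect_equal(total_loss(v[1], v[2], v[3], v[4], v[5], w),
                 oracle(v[1], v[2], v[3], v[4], v[5], v[6], v[7], v[8], 1),
                 tolerance = 1e-12)
  }
})

test_that("the consistency ramp is non-decreasing and bounded", {
  r <- vapply(1:20, function(e) noisyseg:::ramp_multiplier(e, 20, 0.5),
              numeric(1))
  expect_true(all(diff(r) >= 0))
  expect_true(all(r >= 0 & r <= 1))
  expect_equal(r[20], 1)
  expect_lt(r[1], 0.05)
  expect_equal(noisyseg:::ramp_multiplier(1, 10, 0), 1)
})

test_that("supervised training reduces the loss on clean phantoms", {
  wins <- 0
  for (sd in 1:3) {
    samples <- lapply(1:8, function(i)
      generate_phantom(tiny_spec(), seed = sd * 100 + i))
    fit <- mpvt(samples, backbone = unet_config(depth = 3, base_width = 4),
                weights = loss_weights(beta_ada = 0, beta_reg = 0,
                                       beta_semi = 0),
                control = desk_control(epochs = 6, seed = sd))
    if (tail(fit$log$loss_total, 1) < fit$log$loss_total[1]) wins <- wins + 1
  }
  expect_gte(wins, 2)
})

test_that("training aborts when the supervised loss has no contributors", {
  s <- generate_phantom(tiny_spec(), 1)
  noisy_only <- list(image_sample("n1", s$image, s$mask, purity = "noisy",
                                  corruption_log = "synthetic"))
  expect_error(mpvt(noisy_only, backbone = unet_config(2, 2),
                    weights = loss_weights(beta_ada = 1)),
               "supervised loss")
  # but runs when beta_ada = 0 routes noisy masks into supervision
  fit <- mpvt(noisy_only, backbone = unet_config(2, 2),
              weights = loss_weights(beta_ada = 0, beta_reg = 0,
                                     beta_semi = 0),
              control = desk_control(epochs = 1))
  expect_s3_class(fit, "mpvt_fit")
})

test_that("plateaued validation triggers learning-rate decay by the configured factor", {
  samples <- lapply(1:4, function(i) generate_phantom(tiny_spec(), i))
  val <- lapply(5:6, function(i) generate_phantom(tiny_spec(), i))
  ctl <- training_config(lr = 1e-13, batch_size = 2, accum = 1,
                         plateau_factor = 10, patience = 2, epochs = 8,
                         seed = 1)
  fit <- mpvt(samples, val = val, backbone = unet_config(2, 2),
              weights = loss_weights(0, 0, 0), control = ctl)
  # with a vanishing learning rate nothing improves, so the schedule must
  # have cut the rate at least once by the final epoch
  expect_lt(tail(fit$log$lr, 1), 1e-13)
  expect_true(any(abs(fit$log$lr - 1e-14) < 1e-20))
})

test_that("zero-weight full machinery reproduces the supervised run bit-for-bit", {
  d <- tiny_trio()
  ctl <- desk_control(epochs = 3, seed = 9)
  zw <- loss_weights(beta_ada = 0, beta_reg = 0, beta_semi = 0)
  fA <- mpvt(d$train, val = d$val, backbone = unet_config(3, 4),
             weights = zw, control = ctl, teachers = teacher_ensemble())
  fB <- mpvt(d$train, val = d$val, backbone = unet_config(3, 4),
             weights = zw, control = ctl,
             teachers = teacher_ensemble(K = 1, update_mask_rate = 1,
                                         activation_fracs = 0))
  expect_identical(noisyseg:::par_flatten(fA$model$params),
                   noisyseg:::par_flatten(fB$model$params))
  expect_identical(fA$log$loss_total, fB$log$loss_total)
})

test_that("fit objects expose the standard methods", {
  d <- tiny_trio()
  fit <- mpvt(d$train, val = d$val, backbone = unet_config(3, 4),
              weights = loss_weights(), control = desk_control(epochs = 2,
                                                               seed = 3))
  expect_output(print(fit), "beta_ada")
  expect_output(summary(fit), "epoch")
  expect_true(is.data.frame(fit$log))

  pr <- predict(fit, generate_phantom(tiny_spec(), 99)$image)
  expect_true(all(pr >= 0 & pr <= 1))
  mk <- predict(fit, generate_phantom(tiny_spec(), 99)$image, type = "mask")
  expect_true(all(mk %in% c(0, 1)))

  preds <- predict(fit, d$test)
  expect_length(preds, 4)
  expect_named(preds)

  sc <- evaluate_fit(fit, d$test)
  expect_s3_class(sc, "score_table")
  expect_equal(nrow(sc), 4)
  expect_true(all(sc$svd == 100 - sc$dsc))

  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(fit))
})
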