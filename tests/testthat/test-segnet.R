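test_that("forward passes are deterministic, ranged and shape-preserving", {
  for (depth in 2:3) {
    cfg <- unet_config(depth = depth, base_width = 4, dropout_rate = 0.2)
    m <- unet_init(cfg, seed = 1)
    img <- rand_prob(16, 16, depth)
    a <- unet_forward(m, img)
    b <- unet_forward(m, img)
    expect_identical(a$prob, b$prob)
    expect_identical(a$cmap$p_fg_given_fg, b$cmap$p_fg_given_fg)
    expect_identical(dim(a$prob), dim(img))
    expect_identical(dim(a$cmap$p_fg_given_bg), dim(img))
    expect_true(all(a$prob >= 0 & a$prob <= 1))
    expect_true(all(a$cmap$p_fg_given_fg >= 0 & a$cmap$p_fg_given_fg <= 1))
  }
  expect_error(unet_forward(unet_init(unet_config(4, 4), 1),
                            matrix(0.5, 18, 18)), "divisible")
})

test_that("identical seeds reproduce initialization; different seeds differ", {
  cfg <- unet_config(depth = 2, base_width = 4)
  expect_identical(unet_init(cfg, 5)$params, unet_init(cfg, 5)$params)
  expect_false(identical(unet_init(cfg, 5)$params, unet_init(cfg, 6)$params))
})

test_that("stochastic forward passes differ across repeats", {
  cfg <- unet_config(depth = 3, base_width = 8, dropout_rate = 0.3)
  m <- unet_init(cfg, seed = 2)
  img <- rand_prob(16, 16, 9)
  outs <- lapply(1:10, function(k)
    unet_forward(m, img, stochastic = TRUE, seed = k)$prob)
  distinct <- length(unique(vapply(outs, function(o) o[1, 1], numeric(1))))
  expect_gt(distinct, 5)
  # same stochastic seed reproduces
  expect_identical(unet_forward(m, img, stochastic = TRUE, seed = 3)$prob,
                   unet_forward(m, img, stochastic = TRUE, seed = 3)$prob)
})

test_that("feature perturbation changes the output of both heads", {
  cfg <- unet_config(depth = 2, base_width = 4, dropout_rate = 0)
  m <- unet_init(cfg, seed = 4)
  img <- rand_prob(8, 8, 2)
  base <- unet_forward(m, img)
  pert <- unet_forward(m, img, feature_perturbation = list(rate = 0.5),
                       seed = 7)
  expect_false(identical(base$prob, pert$prob))
  expect_false(identical(base$cmap$p_fg_given_bg, pert$cmap$p_fg_given_bg))
})

test_that("backpropagation matches finite differences", {
  cfg <- unet_config(depth = 2, base_width = 2, dropout_rate = 0)
  m <- unet_init(cfg, seed = 3)
  img <- rand_prob(8, 8, 11)
  tgt <- rand_mask(8, 8, 0.4, 12)
  ntg <- rand_mask(8, 8, 0.5, 13)
  loss_fn <- function(model) {
    fw <- unet_forward(model, img)
    ag <- noisyseg:::adaptor_grads(fw$prob, fw$cmap, ntg, beta_reg = 0.1,
                                   dice_weight = 0.5)
    seg_loss(fw$prob, tgt)$total + 0.7 * (ag$l_ada$total + 0.1 * ag$sigma)
  }
  fw <- unet_forward(m, img, want_cache = TRUE)
  ag <- noisyseg:::adaptor_grads(fw$prob, fw$cmap, ntg, beta_reg = 0.1,
                                 dice_weight = 0.5)
  gprob <- noisyseg:::seg_loss_grad(fw$prob, tgt) + 0.7 * ag$gpred
  gcmap <- list(0.7 * ag$gcmap[[1]], 0.7 * ag$gcmap[[2]])
  gv <- noisyseg:::par_flatten(unet_backward(m, fw$cache, gprob, gcmap))
  pv <- noisyseg:::par_flatten(m$params)
  idx <- noisyseg:::with_seed(1, sample(length(pv), 30))
  eps <- 1e-4
  for (i in idx) {
    p1 <- pv; p1[i] <- p1[i] + eps
    p2 <- pv; p2[i] <- p2[i] - eps
    ma <- m; ma$params <- noisyseg:::par_unflatten(p1, m$params)
    mb <- m; mb$params <- noisyseg:::par_unflatten(p2, m$params)
    num <- (loss_fn(ma) - loss_fn(mb)) / (2 * eps)
    expect_equal(gv[i], num, tolerance = 1e-5)
  }
})

test_that("every parameter group receives gradient from the combined loss", {
  cfg <- unet_config(depth = 3, base_width = 4, dropout_rate = 0)
  m <- unet_init(cfg, seed = 8)
  img <- rand_prob(16, 16, 20)
  tgt <- rand_mask(16, 16, 0.3, 21)
  ntg <- rand_mask(16, 16, 0.5, 22)
  fw <- unet_forward(m, img, want_cache = TRUE)
  ag <- noisyseg:::adaptor_grads(fw$prob, fw$cmap, ntg, beta_reg = 0.1,
                                 dice_weight = 1)
  gprob <- noisyseg:::seg_loss_grad(fw$prob, tgt) + ag$gpred
  g <- unet_backward(m, fw$cache, gprob, ag$gcmap)
  for (nm in names(g)) {
    expect_gt(sum(abs(g[[nm]]$W)), 0, label = paste0("grad W of ", nm))
    expect_gt(sum(abs(g[[nm]]$b)), 0, label = paste0("grad b of ", nm))
  }
})

test_that("checkpoints round-trip parameters and configuration", {
  cfg <- unet_config(depth = 2, base_width = 4, dropout_rate = 0.05)
  m <- unet_init(cfg, seed = 6)
  path <- file.path(withr::local_tempdir(), "ck.rds")
  save_checkpoint(m, path)
  m2 <- load_checkpoint(path)
  expect_equal(m2$config$depth, 2L)
  expect_equal(m2$config$dropout_rate, 0.05)
  img <- rand_prob(8, 8, 30)
  expect_identical(unet_forward(m, img)$prob, unet_forward(m2, img)$prob)
})
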