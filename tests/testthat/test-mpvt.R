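test_that("identity perturbation settings leave image and mask unchanged", {
  s <- generate_phantom(tiny_spec(), 1)
  out <- perturb(s$image, s$mask, identity_perturbation_spec(), "weak", 5)
  expect_identical(out$image, s$image)
  expect_identical(out$mask, s$mask)
  outs <- perturb(s$image, s$mask, identity_perturbation_spec(), "strong", 5)
  expect_identical(outs$image, s$image)
})

test_that("flips are involutions under record replay", {
  s <- generate_phantom(tiny_spec(), 2)
  rec <- list(hflip = TRUE, vflip = FALSE, angle = 0, dy = 0L, dx = 0L)
  once <- apply_geometric(s$image, rec, "bilinear")
  twice <- apply_geometric(once, rec, "bilinear")
  expect_identical(twice, s$image)
  mrec <- list(hflip = TRUE, vflip = TRUE, angle = 0, dy = 0L, dx = 0L)
  expect_identical(apply_geometric(apply_geometric(s$mask, mrec, "nearest"),
                                   mrec, "nearest"), s$mask)
})

test_that("strong views share the weak view's geometry; photometrics spare the mask", {
  s <- generate_phantom(tiny_spec(), 3)
  spec <- perturbation_spec()
  for (sd in 1:20) {
    w <- perturb(s$image, s$mask, spec, "weak", sd)
    st <- perturb(s$image, s$mask, spec, "strong", sd)
    expect_identical(st$mask, w$mask)
    expect_identical(st$record[c("hflip", "vflip", "angle", "dy", "dx")],
                     w$record[c("hflip", "vflip", "angle", "dy", "dx")])
  }
})

test_that("geometric transforms move image and mask together", {
  s <- generate_phantom(tiny_spec(), 4)
  spec <- perturbation_spec(hflip_p = 1, vflip_p = 0, max_translate = 0,
                            max_rotate = 0)
  w <- perturb(s$image, s$mask, spec, "weak", 1)
  expect_identical(w$image, s$image[, ncol(s$image):1])
  expect_identical(w$mask, s$mask[, ncol(s$mask):1])
})

test_that("masked EMA updates follow the per-parameter mask law", {
  t0 <- rep(1, 1000); s0 <- rep(0, 1000)
  expect_identical(masked_ema_update(t0, s0, 0.9, 0, seed = 1), t0)
  expect_identical(masked_ema_update(t0, s0, 0, 1, seed = 1), s0)
  expect_equal(masked_ema_update(1, 0, 0.9, 1, seed = 1), 0.9)
  half <- masked_ema_update(t0, s0, 0.9, 0.5, seed = 2)
  expect_setequal(unique(half), c(1, 0.9))
  expect_lt(abs(mean(half == 0.9) - 0.5), 4 * sqrt(0.25 / 1000))
  expect_error(masked_ema_update(1:3, 1:4, 0.9, 1), "congruent")
})

test_that("teacher drift per step is bounded by (1 - alpha) * m in expectation", {
  nrep <- 200
  t0 <- runif(nrep); s0 <- runif(nrep)
  alpha <- 0.99; m <- 0.5
  upd <- masked_ema_update(t0, s0, alpha, m, seed = 3)
  drift <- mean(abs(upd - t0))
  bound <- (1 - alpha) * mean(abs(t0 - s0))   # expected drift = m * bound
  expect_lt(drift, bound)                      # strictly below full-EMA drift
  expect_lt(abs(drift - m * bound), 0.5 * bound)
})

test_that("ensemble predictions average the teachers", {
  cfg <- unet_config(depth = 2, base_width = 4)
  model <- unet_init(cfg, seed = 1)
  img <- rand_prob(8, 8, 40)
  pv <- noisyseg:::par_flatten(model$params)

  single <- ensemble_predict(list(pv), model, img)
  expect_equal(single, unet_forward(model, img)$prob, tolerance = 1e-12)

  trip <- ensemble_predict(list(pv, pv, pv), model, img)
  expect_equal(trip, single, tolerance = 1e-12)

  # two constant teachers at 0.2 and 0.8 average to 0.5
  mk_const <- function(p) {
    v <- numeric(length(pv))
    tpl <- model$params
    z <- noisyseg:::par_unflatten(v, tpl)
    z$head$b <- noisyseg:::logit(p)
    noisyseg:::par_flatten(z)
  }
  pair <- ensemble_predict(list(mk_const(0.2), mk_const(0.8)), model, img)
  expect_equal(pair, matrix(0.5, 8, 8), tolerance = 1e-12)

  expect_error(ensemble_predict(list(), model, img), "empty")
})

test_that("the two-threshold pseudo-label rule matches its indicator", {
  cfg <- pseudo_label_config(tau1 = 0.9, tau2 = 0.6)
  one <- function(p, y) make_pseudo_label(matrix(p, 1, 1),
                                          matrix(y, 1, 1), cfg)[1, 1]
  expect_equal(one(0.95, 0), 1)
  expect_equal(one(0.7, 1), 1)
  expect_equal(one(0.7, 0), 0)
  expect_equal(one(0.5, 1), 0)

  # exhaustive grid against a direct evaluation of the indicator
  preds <- seq(0, 1, by = 0.05)
  for (tau1 in c(0.5, 0.7, 0.9)) {
    for (tau2 in c(0.5, 0.7, 0.9)) {
      if (tau2 > tau1) next
      cfg2 <- pseudo_label_config(tau1, tau2)
      for (lab in c(0, 1)) {
        got <- vapply(preds, function(p)
          make_pseudo_label(matrix(p, 1, 1), matrix(lab, 1, 1), cfg2)[1, 1],
          numeric(1))
        want <- as.numeric(preds >= tau1 | (preds >= tau2 & lab == 1))
        expect_identical(got, want)
      }
    }
  }
  expect_error(pseudo_label_config(0.5, 0.9), "tau2")
})

test_that("pseudo-labels are monotone in confidence and thresholds", {
  cfg <- pseudo_label_config(0.9, 0.6)
  for (sd in 1:10) {
    pred <- rand_prob(8, 8, sd)
    lab <- rand_mask(8, 8, 0.4, sd + 10)
    base <- make_pseudo_label(pred, lab, cfg)
    bumped <- pred + 0.05
    bumped[bumped > 1] <- 1
    up <- make_pseudo_label(bumped, lab, cfg)
    expect_true(all(up - base >= 0))
    looser <- make_pseudo_label(pred, lab, pseudo_label_config(0.8, 0.5))
    expect_true(all(looser - base >= 0))
  }
})

test_that("semi loss is definitionally the supervised loss on pseudo-labels", {
  p <- rand_prob(8, 8, 1)
  ps <- rand_mask(8, 8, 0.3, 2)
  expect_equal(semi_loss(p, ps)$total, seg_loss(p, ps)$total)
  expect_equal(semi_loss(matrix(0.5, 8, 8), ps)$ce, log(2), tolerance = 1e-12)
  hard <- rand_mask(8, 8, 0.4, 3)
  expect_lt(semi_loss(hard, hard)$ce, 1e-6)
})
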