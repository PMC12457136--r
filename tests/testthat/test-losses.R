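test_that("the adaptation transform follows the law of total probability", {
  p <- rand_prob(6, 6, 1)
  id <- corruption_map(matrix(1, 6, 6), matrix(0, 6, 6))
  expect_equal(adapt(p, id), p)

  cm <- corruption_map(rand_prob(6, 6, 2), rand_prob(6, 6, 3))
  expect_equal(adapt(matrix(1, 6, 6), cm), cm$p_fg_given_fg)
  expect_equal(adapt(matrix(0, 6, 6), cm), cm$p_fg_given_bg)

  one <- matrix(0.6, 1, 1)
  cm1 <- corruption_map(matrix(0.9, 1, 1), matrix(0.1, 1, 1))
  expect_equal(adapt(one, cm1)[1, 1], 0.6 * 0.9 + 0.4 * 0.1)  # 0.58

  expect_error(adapt(matrix(0.5, 2, 2),
                     corruption_map(matrix(1, 3, 3), matrix(0, 3, 3))),
               "shapes")
})

test_that("adapt is monotone and bounded by the corruption-map endpoints", {
  for (sd in 1:10) {
    a <- rand_prob(5, 5, sd)
    b <- a * rand_prob(5, 5, sd + 50)      # b <= a pixel-wise
    cm <- corruption_map(a, b)
    p1 <- rand_prob(5, 5, sd + 100)
    p2 <- p1 + 0.1
    p2[p2 > 1] <- 1
    y1 <- adapt(p1, cm); y2 <- adapt(p2, cm)
    expect_true(all(y2 - y1 >= -1e-12))
    expect_true(all(y1 >= pmin(a, b) - 1e-12 & y1 <= pmax(a, b) + 1e-12))
  }
})

# independent per-pixel double-loop oracle for the CE + soft-Dice loss
brute_seg_loss <- function(pred, target, eps_dice = 1, eps_ce = 1e-7) {
  ce <- 0; inter <- 0; sp <- 0; st <- 0
  for (i in seq_len(nrow(pred))) {
    for (j in seq_len(ncol(pred))) {
      p <- min(1 - eps_ce, max(eps_ce, pred[i, j]))
      t <- target[i, j]
      ce <- ce - t * log(p) - (1 - t) * log(1 - p)
      inter <- inter + pred[i, j] * t
      sp <- sp + pred[i, j]; st <- st + t
    }
  }
  ce / length(pred) + 1 - (2 * inter + eps_dice) / (sp + st + eps_dice)
}

test_that("seg_loss matches a brute-force oracle and its closed forms", {
  tgt <- rand_mask(8, 8, 0.4, 7)
  l_perfect <- seg_loss(tgt, tgt)
  expect_lt(l_perfect$ce, 1e-6)
  expect_lt(l_perfect$dice, 1 / (2 * sum(tgt)))  # epsilon-induced bound

  l_half <- seg_loss(matrix(0.5, 8, 8), tgt)
  expect_equal(l_half$ce, log(2), tolerance = 1e-12)

  for (sd in 1:5) {
    p <- rand_prob(8, 8, sd)
    t <- rand_mask(8, 8, 0.5, sd + 10)
    expect_equal(seg_loss(p, t)$total, brute_seg_loss(p, t),
                 tolerance = 1e-10)
  }
  expect_error(seg_loss(matrix(0.5, 2, 2), matrix(0.5, 2, 2)), "0, 1")
})

test_that("seg_loss_grad matches numerical differentiation", {
  p <- rand_prob(6, 6, 3) * 0.9 + 0.05
  t <- rand_mask(6, 6, 0.5, 4)
  g <- noisyseg:::seg_loss_grad(p, t)
  eps <- 1e-7
  for (k in c(1, 9, 17, 30)) {
    p1 <- p; p1[k] <- p1[k] + eps
    p2 <- p; p2[k] <- p2[k] - eps
    num <- (seg_loss(p1, t)$total - seg_loss(p2, t)$total) / (2 * eps)
    expect_equal(g[k], num, tolerance = 1e-5)
  }
})

test_that("adaptor loss is the supervised loss of the adapted map", {
  p <- rand_prob(8, 8, 1)
  t <- rand_mask(8, 8, 0.4, 2)
  id <- corruption_map(matrix(1, 8, 8), matrix(0, 8, 8))
  expect_equal(adaptor_loss(p, id, t)$total, seg_loss(p, t)$total)
  cm <- corruption_map(rand_prob(8, 8, 3), rand_prob(8, 8, 4))
  expect_equal(adaptor_loss(p, cm, t)$total, seg_loss(adapt(p, cm), t)$total)
})

test_that("a truthful corruption map beats raw prediction against noisy masks", {
  s <- generate_phantom(tiny_spec(), 9)
  truth <- s$mask
  pred <- truth                                   # perfect clean prediction
  rho <- 0.3
  cm_true <- corruption_map(matrix(1 - rho, 32, 32), matrix(rho, 32, 32))
  l_ada <- l_raw <- numeric(100)
  for (sd in 1:100) {
    noisy <- apply_transition_noise(truth, symmetric_transition(rho), sd)
    l_ada[sd] <- adaptor_loss(pred, cm_true, noisy)$total
    l_raw[sd] <- seg_loss(pred, noisy)$total
  }
  expect_lt(mean(l_ada), mean(l_raw))
})

test_that("shortcut penalty is the mean squared raw-adapted gap", {
  p <- rand_prob(16, 16, 5)
  expect_equal(shortcut_penalty(p, p)$total, 0)
  expect_equal(shortcut_penalty(matrix(1, 1, 1), matrix(0, 1, 1))$total, 1)
  a <- rand_prob(16, 16, 6)
  brute <- mean(vapply(seq_along(p), function(k) (p[k] - a[k])^2, numeric(1)))
  expect_equal(shortcut_penalty(p, a)$total, brute, tolerance = 1e-12)
})
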