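test_that("symmetric transition matrices are row-stochastic with equal off-diagonals", {
  expect_equal(unclass(symmetric_transition(0, 2)), diag(2),
               ignore_attr = TRUE)
  t2 <- symmetric_transition(0.3, 2)
  expect_equal(unclass(t2), matrix(c(0.7, 0.3, 0.3, 0.7), 2, 2),
               ignore_attr = TRUE)
  t4 <- symmetric_transition(0.3, 4)
  expect_true(all(abs(t4[row(t4) != col(t4)] - 0.1) < 1e-12))
  expect_equal(rowSums(t4), rep(1, 4), tolerance = 1e-12)
  expect_error(symmetric_transition(1.2), "\\[0, 1\\]")
  expect_error(symmetric_transition(0.3, 1), "c")
})

test_that("asymmetric transition matrices encode the two flip rates", {
  expect_equal(unclass(asymmetric_transition(0, 0)), diag(2),
               ignore_attr = TRUE)
  t <- asymmetric_transition(0.1, 0.4)
  expect_equal(unclass(t), matrix(c(0.9, 0.4, 0.1, 0.6), 2, 2),
               ignore_attr = TRUE)
  for (r in list(c(0.2, 0.8), c(0, 1), c(0.33, 0.41))) {
    expect_equal(rowSums(asymmetric_transition(r[1], r[2])), c(1, 1))
  }
  expect_error(asymmetric_transition(-0.1, 0.2), "\\[0, 1\\]")
})

test_that("transition noise redraws labels from the right row", {
  m <- rand_mask(16, 16, 0.4)
  expect_identical(apply_transition_noise(m, symmetric_transition(0, 2), 1), m)
  flip_all <- asymmetric_transition(1, 1)
  expect_identical(apply_transition_noise(m, flip_all, 1), 1 - m)
  expect_identical(apply_transition_noise(m, symmetric_transition(0.4), 9),
                   apply_transition_noise(m, symmetric_transition(0.4), 9))
  expect_error(apply_transition_noise(matrix(2, 2, 2),
                                      symmetric_transition(0.1), 1), "0, 1")
})

test_that("empirical flip rates match the nominal rate within 4-sigma binomial bounds", {
  mask <- matrix(0, 128, 128)
  n <- length(mask)
  rho <- 0.3
  tol <- 4 * sqrt(rho * (1 - rho) / n)
  t <- symmetric_transition(rho)
  for (sd in 1:50) {
    out <- apply_transition_noise(mask, t, seed = sd)
    expect_lt(abs(mean(out) - rho), tol)
  }
})

test_that("corruption fields combine base, boundary and intensity terms", {
  s <- generate_phantom(tiny_spec(), 4)
  flat <- field_spec(b01 = 0.05, b10 = 0.12, boundary_weight = 0,
                     intensity_weight = 0)
  f <- build_corruption_field(s$image, s$mask, flat)
  expect_true(all(f$p01 == 0.05))
  expect_true(all(f$p10 == 0.12))

  fs <- field_spec(b01 = 0.02, b10 = 0.02, boundary_weight = 0.3,
                   boundary_dist = 2, intensity_weight = 0)
  fb <- build_corruption_field(s$image, s$mask, fs)
  d <- noisyseg:::boundary_distance(s$mask)
  band <- d <= 2
  expect_gte(mean(fb$p10[band]), mean(fb$p10[!band]))

  # two-pixel construction: a background pixel at exactly the tumour
  # reference intensity draws more false-positive probability than a
  # maximally different one
  img <- matrix(c(0.30, 1.0), 1, 2)
  msk <- matrix(0, 1, 2)
  fi <- build_corruption_field(img, msk,
                               field_spec(b01 = 0.02, boundary_weight = 0,
                                          intensity_weight = 0.2,
                                          intensity_ref = 0.30))
  expect_gt(fi$p01[1, 1], fi$p01[1, 2])
  expect_true(all(fi$p01 >= 0 & fi$p01 <= 1))
})

test_that("field noise flips per-pixel with the mapped probabilities", {
  m <- rand_mask(20, 20, 0.3, seed = 2)
  zero <- corruption_field(matrix(0, 20, 20), matrix(0, 20, 20))
  expect_identical(apply_field_noise(m, zero, 1), m)
  kill_fg <- corruption_field(matrix(0, 20, 20), matrix(1, 20, 20))
  expect_true(all(apply_field_noise(m, kill_fg, 1) == 0))
  expect_error(apply_field_noise(m, corruption_field(matrix(0, 5, 5),
                                                     matrix(0, 5, 5)), 1),
               "shapes")
})

test_that("constant fields reproduce transition-noise statistics", {
  mask <- matrix(rep(c(0, 1), each = 8192), 128, 128)
  f <- corruption_field(matrix(0.2, 128, 128), matrix(0.35, 128, 128))
  t <- asymmetric_transition(0.2, 0.35)
  field_rate <- transition_rate <- numeric(50)
  for (sd in 1:50) {
    field_rate[sd] <- mean(apply_field_noise(mask, f, sd) != mask)
    transition_rate[sd] <- mean(apply_transition_noise(mask, t, sd + 500) != mask)
  }
  exp_rate <- (0.2 + 0.35) / 2
  se <- sqrt(exp_rate * (1 - exp_rate) / length(mask) / 50)
  expect_lt(abs(mean(field_rate) - mean(transition_rate)), 6 * se)
  expect_lt(abs(mean(field_rate) - exp_rate), 6 * se)
})

test_that("structured corruptions behave as their geometry dictates", {
  m <- generate_phantom(tiny_spec(vessel_count = 0), 6)$mask

  expect_identical(apply_structured_corruption(m, "shift",
                                               list(dy = 0, dx = 0)), m)
  expect_identical(apply_structured_corruption(m, "bleed", list(radius = 0)), m)
  expect_identical(apply_structured_corruption(m, "truncate",
                                               list(fraction = 0)), m)
  expect_identical(apply_structured_corruption(m, "deform",
                                               list(magnitude = 0), 3), m)
  expect_identical(apply_structured_corruption(m, "speckle",
                                               list(density = 0), 3), m)

  sh <- apply_structured_corruption(m, "shift", list(dy = 3, dx = -2))
  expect_equal(sh[4:32, 1:30], m[1:29, 3:32])
  expect_true(all(sh[1:3, ] == 0))

  areas <- vapply(0:3, function(r)
    sum(apply_structured_corruption(m, "bleed", list(radius = r))),
    numeric(1))
  expect_true(all(diff(areas) >= 0))

  m64 <- matrix(1, 64, 64)
  tr <- apply_structured_corruption(m64, "truncate",
                                    list(fraction = 0.5, edge = "bottom"))
  expect_true(all(tr[33:64, ] == 0))
  expect_true(all(tr[1:32, ] == 1))

  for (kind in c("deform", "speckle")) {
    a <- apply_structured_corruption(m, kind, list(), seed = 5)
    b <- apply_structured_corruption(m, kind, list(), seed = 5)
    expect_identical(a, b)
    expect_true(all(a %in% c(0, 1)))
    expect_identical(dim(a), dim(m))
  }
  expect_error(apply_structured_corruption(m, "melt"), "unknown")
})

test_that("corruption plans compose deterministically and the empty plan is the identity", {
  s <- generate_phantom(tiny_spec(), 8)
  empty <- corruption_plan()
  out <- apply_corruption_plan(s$mask, empty, seed = 1)
  expect_equal(matrix(out, nrow(out)), s$mask, ignore_attr = TRUE)

  plan <- default_corruption_plan()
  a <- apply_corruption_plan(s$mask, plan, image = s$image, seed = 3)
  b <- apply_corruption_plan(s$mask, plan, image = s$image, seed = 3)
  expect_identical(a, b)
  expect_length(attr(a, "corruption_log"), 3)
  expect_false(identical(matrix(a, nrow(a)), s$mask))

  withfield <- corruption_plan(step_field(field_spec()))
  expect_error(apply_corruption_plan(s$mask, withfield, seed = 1), "image")
})
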