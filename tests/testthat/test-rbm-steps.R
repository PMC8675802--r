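test_that("energy evaluates the bilinear form and its linearity", {
  expect_equal(rbm_energy(c(0, 0), c(0, 0), matrix(1, 2, 2), c(1, 1), c(1, 1)), 0)
  expect_equal(rbm_energy(1, 1, matrix(2), 1, 3), -6)

  withr::with_seed(3, {
    v <- rbinom(4, 1, 0.5); h <- rbinom(4, 1, 0.5)
    w <- matrix(rnorm(16), 4); b <- rnorm(4); cc <- rnorm(4)
  })
  e1 <- rbm_energy(v, h, w, b, cc)
  e2 <- rbm_energy(v, h, 2 * w, b, cc)
  interaction <- e1 + sum(b * v) + sum(cc * h)
  expect_equal(e2, e1 + interaction) # doubling w doubles only the interaction term
  expect_error(rbm_energy(c(1, 0), c(1), matrix(1, 2, 2), c(0, 0), 0), "matrix")
})

test_that("pair initialization is bounded, mirrored and seed-stable", {
  st <- init_pair(6, seed = 42)
  expect_true(all(abs(st$w1) <= 1 / 6))
  expect_identical(st$w1, st$w2)
  expect_identical(st$bias, numeric(6))
  expect_identical(st, init_pair(6, seed = 42))
  expect_error(init_pair(0), "positive")

  # Monte-Carlo check of the uniform[-1/n, 1/n] claim
  n <- 10
  entries <- unlist(lapply(1:10, function(s) init_pair(n, seed = s)$w1)) # 1000 per seed
  entries <- c(entries, unlist(lapply(11:110, function(s) init_pair(n, seed = s)$w1)))
  se <- (2 / n) / sqrt(12) / sqrt(length(entries))
  expect_lt(abs(mean(entries)), 3 * se)
  expect_lt(max(entries), 1 / n)
  expect_gt(min(entries), -1 / n)
  expect_gt(max(entries), 0.95 / n)
  expect_lt(min(entries), -0.95 / n)
})

test_that("forward pass applies bias, logistic and thresholding", {
  f <- forward_pass(c(0.3, 0.9), matrix(0, 2, 2), c(0, 0), c(0.5, 0.5))
  expect_equal(f$act, c(0.5, 0.5))
  expect_equal(f$state, c(FALSE, FALSE)) # strict inequality

  w <- matrix(c(0.5, 0.25, -0.5, 0.25), 2, 2)
  f <- forward_pass(c(1, 0), w, c(0, 0), c(0.5, 0.5))
  expect_equal(f$pre_act, c(0.5, -0.5))
  expect_equal(f$act, plogis(c(0.5, -0.5)), tolerance = 1e-12)
  expect_equal(round(f$act, 4), c(0.6225, 0.3775))
  expect_equal(f$state, c(TRUE, FALSE))

  # activations strictly increase with pre-activations
  sweep <- seq(-4, 4, by = 0.5)
  acts <- vapply(sweep, function(s) {
    forward_pass(c(s, 0), diag(2), c(0, 0), c(0.5, 0.5))$act[1]
  }, numeric(1))
  expect_true(all(diff(acts) > 0))
})

test_that("backward pass reconstructs through t(w) by default", {
  b <- backward_pass(c(0.2, 0.8), matrix(0, 2, 2), c(0, 0))
  expect_equal(b$recon_act, c(0.5, 0.5))
  expect_equal(b$hidden_act, c(0.5, 0.5))

  h <- c(0.3, 0.6, 0.9)
  b <- backward_pass(h, diag(3) / 3, numeric(3))
  expect_equal(b$recon_act, plogis(h / 3))

  wsym <- matrix(c(0.2, 0.1, 0.1, -0.3), 2, 2)
  expect_equal(backward_pass(c(0.4, 0.6), wsym, c(0, 0), TRUE),
               backward_pass(c(0.4, 0.6), wsym, c(0, 0), FALSE))
  wasym <- matrix(c(0.2, 0.5, -0.1, -0.3), 2, 2)
  expect_false(isTRUE(all.equal(
    backward_pass(c(0.4, 0.6), wasym, c(0, 0), TRUE)$recon_act,
    backward_pass(c(0.4, 0.6), wasym, c(0, 0), FALSE)$recon_act)))
})

test_that("associations are outer products of rank at most one", {
  expect_equal(associations(c(0, 0, 0), c(0.1, 0.2, 0.3)), matrix(0, 3, 3))
  expect_equal(associations(c(1, 2), c(0.5, 0.25)),
               matrix(c(0.5, 1.0, 0.25, 0.5), 2, 2))
  withr::with_seed(1, {
    for (i in 1:5) {
      a <- runif(5); h <- runif(5)
      expect_lte(qr(associations(a, h))$rank, 1L)
    }
  })
  expect_error(associations(1:3, 1:2), "length")
})

test_that("reconstruction error is the elementwise sum of squares", {
  expect_equal(reconstruction_error(c(1, 2), c(1, 2)), 0)
  expect_equal(reconstruction_error(c(1, 0), c(0, 1)), 2)
  withr::with_seed(2, {
    a <- runif(7); b <- runif(7)
  })
  loop <- 0
  for (i in seq_along(a)) loop <- loop + (a[i] - b[i])^2
  expect_equal(reconstruction_error(a, b), loop)
})

test_that("the contrastive update scales the association gap", {
  w <- matrix(c(1, 0, 0, 1), 2)
  f <- matrix(2, 2, 2); b <- matrix(1, 2, 2)
  expect_equal(update_weights(w, f, b, 0, 2), w)
  expect_equal(update_weights(w, f, f, 0.5, 2), w)
  expect_equal(update_weights(matrix(1), matrix(2), matrix(1), 0.5, 1), matrix(1.5))
  expect_error(update_weights(w, matrix(1), b, 0.1, 2), "dimensions")
})

test_that("strengths average activations over jointly active units", {
  all_on <- matched_strengths(c(0.2, 0.4), c(0.6, 0.8), c(TRUE, TRUE), c(TRUE, TRUE))
  expect_equal(all_on$strength_a, 0.3)
  expect_equal(all_on$strength_b, 0.7)

  disjoint <- matched_strengths(c(0.9, 0.9), c(0.9, 0.9),
                                c(TRUE, FALSE), c(FALSE, TRUE))
  expect_identical(disjoint$matched_units, 0L)
  expect_true(is.na(disjoint$strength_a) && is.na(disjoint$strength_b))

  ex <- matched_strengths(c(0.9, 0.2, 0.8), c(0.7, 0.9, 0.6),
                          c(TRUE, FALSE, TRUE), c(TRUE, TRUE, TRUE))
  expect_equal(ex$strength_a, 0.85)
  expect_equal(ex$strength_b, 0.65)
  expect_identical(ex$matched_units, 2L)
})
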