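test_that("roi_align pools constants to constants with a fixed output shape", {
  f <- array(3.7, c(16, 16, 2))
  for (box in list(c(0, 0, 16, 16), c(2.3, 4.1, 9.9, 12.5), c(5, 5, 6, 6))) {
    p <- roi_align(f, box, out_size = 7)
    expect_equal(dim(p), c(7, 7, 2))
    expect_equal(max(abs(p - 3.7)), 0)
  }
  expect_error(roi_align(f, c(4, 4, 4, 8)), "degenerate")
})

test_that("integer-aligned bins on a ramp equal direct bin averages", {
  f <- array(0, c(4, 4, 1)); f[, , 1] <- matrix(1:16, 4, 4)
  p <- roi_align(f, c(0, 0, 4, 4), out_size = 2)
  expect_equal(p[, , 1], rbind(c(mean(f[1:2, 1:2, 1]), mean(f[1:2, 3:4, 1])),
                               c(mean(f[3:4, 1:2, 1]), mean(f[3:4, 3:4, 1]))))
})

test_that("roi_align is linear in the feature map", {
  set.seed(2)
  F1 <- array(rnorm(10 * 10 * 3), c(10, 10, 3))
  F2 <- array(rnorm(10 * 10 * 3), c(10, 10, 3))
  box <- c(1.2, 2.7, 8.4, 9.1)
  lhs <- roi_align(2 * F1 - 3 * F2, box, 5)
  rhs <- 2 * roi_align(F1, box, 5) - 3 * roi_align(F2, box, 5)
  expect_lt(max(abs(lhs - rhs)), 1e-12)
})

test_that("softmax probabilities normalize and obey closed forms", {
  set.seed(3)
  prm <- softmax_params(matrix(rnorm(8), 4, 2))
  x <- rnorm(2)
  p <- softmax_probs(x, prm)
  expect_equal(sum(p), 1, tolerance = 1e-9)
  # equal logits -> uniform
  prm0 <- softmax_params(matrix(1, 5, 3))
  expect_equal(softmax_probs(rnorm(3), prm0), rep(1 / 5, 5))
  # k = 2 with logit difference ln 2 -> (2/3, 1/3)
  prm2 <- softmax_params(rbind(c(log(2), 0), c(0, 0)))
  expect_equal(softmax_probs(c(1, 0), prm2), c(2 / 3, 1 / 3))
  # shift invariance
  prms <- softmax_params(prm$theta + 5)
  expect_equal(softmax_probs(x, prms), softmax_probs(x, prm), tolerance = 1e-9)
  xs <- matrix(rnorm(20), 10, 2)
  expect_equal(rowSums(softmax_probs(xs, prm)), rep(1, 10), tolerance = 1e-9)
})

test_that("softmax cost matches closed forms and rejects empty batches", {
  prm0 <- softmax_params(matrix(0, 4, 3))
  batch <- list(x = matrix(rnorm(15), 5, 3), y = c(1L, 4L, 2L, 3L, 1L))
  expect_equal(softmax_loss(batch, prm0), log(4))  # uniform predictions
  expect_error(softmax_loss(list(x = matrix(0, 0, 3), y = integer(0)), prm0),
               "empty")
  expect_error(softmax_loss(list(x = batch$x, y = c(1L, 9L, 1L, 1L, 1L)), prm0),
               "labels")
})

test_that("the analytic softmax gradient matches finite differences", {
  set.seed(11)
  prm <- softmax_params(matrix(rnorm(10, 0, 0.5), 5, 2))
  batch <- list(x = matrix(rnorm(16), 8, 2), y = sample(1:5, 8, replace = TRUE))
  g <- softmax_gradient(batch, prm)
  fd <- finite_diff(function(th)
    softmax_loss(batch, softmax_params(th)), prm$theta)
  expect_lt(max(abs(g - fd)), 1e-4)
  # per-sample contributions sum to zero over classes
  expect_lt(max(abs(colSums(g))), 1e-10)
})

test_that("gradient descent updates and descends", {
  prm <- softmax_params(matrix(c(1, -2, 0.5, 3), 2, 2), alpha = 1)
  expect_equal(sgd_step(prm, matrix(0, 2, 2))$theta, prm$theta)
  expect_equal(sgd_step(prm, prm$theta, alpha = 1)$theta, matrix(0, 2, 2))
  expect_error(sgd_step(prm, prm$theta, alpha = -1), "positive")
  set.seed(13)
  prm <- softmax_params(matrix(rnorm(6), 3, 2), alpha = 0.05)
  batch <- list(x = matrix(rnorm(40), 20, 2), y = sample(1:3, 20, replace = TRUE))
  before <- softmax_loss(batch, prm)
  stepped <- sgd_step(prm, softmax_gradient(batch, prm))
  expect_lte(softmax_loss(batch, stepped), before)
})

test_that("the mask head honours its shape contract and zero-weight behaviour", {
  set.seed(17)
  mh <- build_mask_head(8, 16, num_classes = 2)
  roi <- array(rnorm(14 * 14 * 8), c(14, 14, 8))
  logits <- mask_head_logits(mh, roi)
  expect_equal(dim(logits), c(28, 28, 2))
  mh0 <- build_mask_head(8, 16, num_classes = 1, init = "zero")
  l0 <- mask_head_logits(mh0, roi)
  expect_true(all(l0 == 0))
  expect_true(all(1 / (1 + exp(-l0)) == 0.5))
})

test_that("pasting an all-ones mask covers exactly the rounded box", {
  m <- matrix(1, 28, 28)
  out <- paste_mask(m, c(3.4, 5.6, 11.2, 14.9), 20, 24)
  expect_equal(dim(out), c(20, 24))
  want <- matrix(FALSE, 20, 24)
  want[(6 + 1):15, (3 + 1):11] <- TRUE   # rounded box [3,11) x [6,15)
  expect_identical(out, want)
})

test_that("the multi-task total is an additive sum with logged components", {
  expect_equal(as.numeric(multi_task_loss(0, 0, 0, 0)), 0)
  base <- multi_task_loss(1.5, 0.2, 0.3, 0.4)
  bumped <- multi_task_loss(1.5, 0.2, 0.3 + 0.25, 0.4)
  expect_equal(as.numeric(bumped - base), 0.25)
  expect_equal(unname(attr(base, "components")), c(1.5, 0.2, 0.3, 0.4))
  rl <- rpn_loss(c(1, 0), list(label = c("positive", "negative"),
                               gt_index = c(1L, NA), max_iou = c(1, 0)),
                 matrix(0, 2, 4), matrix(0, 2, 4))
  expect_equal(as.numeric(multi_task_loss(rl, 1, 1, 1)), rl$total + 3)
  expect_error(multi_task_loss(NaN, 0, 0, 0), "non-finite")
})
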