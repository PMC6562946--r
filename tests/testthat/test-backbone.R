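test_that("single-rate sum-merge block equals a hand-composed plain bottleneck", {
  set.seed(5)
  spec <- multipath_block_spec(8, 4, 8, rates = c(1L), merge = "sum")
  blk <- build_block(spec)
  x <- array(rnorm(8 * 12 * 12), c(12, 12, 8))
  got <- block_forward(blk, x, training = TRUE)
  # independent recomposition with the block's extracted weights
  conv1x1 <- function(x, w, b) {
    d <- dim(x)
    y <- matrix(x, d[1] * d[2], d[3]) %*% w
    array(sweep(y, 2, b, "+"), c(d[1], d[2], ncol(w)))
  }
  gnorm <- function(x, groups) {
    d <- dim(x); m <- d[1] * d[2] * (d[3] / groups)
    xm <- x; dim(xm) <- c(m, groups)
    mu <- colMeans(xm); v <- colMeans(sweep(xm, 2, mu)^2)
    xh <- sweep(sweep(xm, 2, mu), 2, 1 / sqrt(v + 1e-5), "*")
    dim(xh) <- d
    xh
  }
  conv3x3 <- function(x, wmat, b) {
    d <- dim(x); H <- d[1]; W <- d[2]; cin <- d[3]
    xp <- array(0, c(H + 2, W + 2, cin)); xp[2:(H + 1), 2:(W + 1), ] <- x
    cout <- ncol(wmat)
    out <- array(0, c(H, W, cout))
    warr <- array(wmat, c(cin, 3, 3, cout))     # channel-fastest layout
    for (r in 1:H) for (cc in 1:W) {
      patch <- xp[r:(r + 2), cc:(cc + 2), , drop = FALSE]
      for (o in 1:cout) {
        s <- 0
        for (ky in 1:3) for (kx in 1:3) for (ci in 1:cin)
          s <- s + patch[ky, kx, ci] * warr[ci, ky, kx, o]
        out[r, cc, o] <- s + b[o]
      }
    }
    out
  }
  h <- pmax(gnorm(conv1x1(x, blk$reduce$w$value, blk$reduce$b$value), blk$reduce_n$groups), 0)
  h <- pmax(gnorm(conv3x3(h, blk$paths[[1]]$conv$w$value, blk$paths[[1]]$conv$b$value),
                  blk$paths[[1]]$norm$groups), 0)
  h <- gnorm(conv1x1(h, blk$restore$w$value, blk$restore$b$value), blk$restore_n$groups)
  want <- pmax(h + x, 0)
  expect_lt(max(abs(got - want)), 1e-5)
})

test_that("stride-1 blocks preserve spatial size for any rate set", {
  set.seed(6)
  for (rates in list(c(1L), c(1L, 2L), c(1L, 2L, 5L))) {
    blk <- build_block(multipath_block_spec(8, 4, 8, rates = rates))
    x <- array(rnorm(8 * 32 * 32), c(32, 32, 8))
    expect_equal(dim(block_forward(blk, x)), c(32, 32, 8))
  }
})

test_that("a zero-initialized block is a pure shortcut", {
  blk <- build_block(multipath_block_spec(6, 3, 6), init = "zero")
  x <- array(abs(rnorm(6 * 10 * 10)), c(10, 10, 6))
  expect_equal(block_forward(blk, x), x)
})

test_that("block spec validation enforces the stated invariants", {
  expect_error(multipath_block_spec(8, 4, 16, shortcut = "identity"),
               "projection")
  expect_error(multipath_block_spec(8, 4, 8, rates = integer(0)), "non-empty")
  expect_error(multipath_block_spec(8, 4, 8, rates = c(2L, 5L)), "contain 1")
})

test_that("weight-layer counting matches the named depths", {
  expect_equal(count_weight_layers(d_resnet64_config()), 64)
  expect_equal(count_weight_layers(d_resnet16_config()), 16)
  expect_equal(count_weight_layers(resnet50_shaped_config()), 49)
  one_block <- backbone_config(
    stem = NULL,
    stages = list(list(blocks = 1L, bottleneck = 4L, channels = 8L)))
  expect_equal(count_weight_layers(one_block), 3)
  expect_equal(count_weight_layers(backbone_config(stem = NULL)), 0)
})

test_that("the channel cap is enforced and declared depth is checked", {
  expect_true(max(vapply(d_resnet64_config()$stages, function(s) s$channels,
                         numeric(1))) <= 256)
  expect_error(backbone_config(
    stages = list(list(blocks = 1L, bottleneck = 8L, channels = 512L))),
    "channel cap")
  expect_error(backbone_config(
    stem = NULL,
    stages = list(list(blocks = 1L, bottleneck = 4L, channels = 8L)),
    declared_depth = 5L), "declared depth")
})

test_that("later stages keep the spatial size of the last downsampled stage", {
  set.seed(8)
  bb <- build_backbone(tiny_backbone_config(), 3)
  x <- array(runif(64 * 64 * 3), c(64, 64, 3))
  outs <- backbone_forward(bb, x, training = TRUE)
  sizes <- t(vapply(outs, function(o) dim(o)[1:2], numeric(2)))
  expect_equal(unname(sizes[2, ]), unname(sizes[3, ]))
  expect_equal(unname(sizes[3, ]), unname(sizes[4, ]))
  expect_equal(unname(sizes[2, ]), c(16, 16))  # 64 / total stride 4
})
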