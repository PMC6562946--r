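# independent influence oracle: convolve indicator kernels by brute force
influence_oracle <- function(stack) {
  field <- matrix(1, 1, 1)
  for (sp in rev(stack)) {
    k <- sp$kernel; r <- sp$rate
    half <- (k - 1) %/% 2 * r
    n <- nrow(field) + 2 * half
    out <- matrix(0, n, n)
    for (i in seq_len(nrow(field))) for (j in seq_len(ncol(field))) {
      if (field[i, j] == 0) next
      for (ky in seq_len(k)) for (kx in seq_len(k)) {
        out[i + (ky - 1) * r, j + (kx - 1) * r] <-
          out[i + (ky - 1) * r, j + (kx - 1) * r] + field[i, j]
      }
    }
    field <- out
  }
  field
}

test_that("closed-form receptive field matches the brute-force oracle", {
  expect_equal(receptive_field(list(dilated_conv_spec(3, 1))), 3)
  expect_equal(receptive_field(list(dilated_conv_spec(3, 2))), 5)
  expect_equal(receptive_field(rep(list(dilated_conv_spec(3, 1)), 3)), 7)
  set.seed(4)
  for (rep in 1:15) {
    depth <- sample(1:4, 1)
    stack <- lapply(seq_len(depth), function(i)
      dilated_conv_spec(3, sample(1:5, 1)))
    oracle_extent <- nrow(influence_oracle(stack))
    expect_equal(receptive_field(stack), oracle_extent)
  }
})

test_that("coverage counts equal the brute-force influence map", {
  set.seed(9)
  for (rep in 1:10) {
    stack <- lapply(seq_len(sample(1:3, 1)), function(i)
      dilated_conv_spec(3, sample(1:4, 1)))
    want <- influence_oracle(stack)
    got <- coverage_map(stack)
    expect_equal(got, want, ignore_attr = TRUE)
  }
})

test_that("a single 3x3 touches all nine neighbourhood positions", {
  cm <- coverage_map(list(dilated_conv_spec(3, 1)))
  expect_equal(cm, matrix(1, 3, 3))
})

test_that("stacked even-rate convolutions leave gridding holes", {
  stack <- rep(list(dilated_conv_spec(3, 2)), 3)
  cm <- coverage_map(stack)
  expect_equal(dim(cm), c(13, 13))
  center <- 7
  offs <- seq_len(13) - center
  odd <- outer(offs, offs, function(a, b) (abs(a) %% 2 == 1) | (abs(b) %% 2 == 1))
  expect_true(all(cm[odd] == 0))        # odd offsets never contribute
  expect_true(any(cm == 0))
  even_lattice <- outer(offs, offs, function(a, b) a %% 2 == 0 & b %% 2 == 0)
  expect_true(all(cm[even_lattice] > 0))
})

test_that("an alternating-rate (1,2,5) stack covers its whole receptive field", {
  stack <- list(dilated_conv_spec(3, 1), dilated_conv_spec(3, 2),
                dilated_conv_spec(3, 5))
  cm <- coverage_map(stack)
  expect_equal(dim(cm), c(17, 17))
  expect_true(all(cm > 0))
})

test_that("an undersized grid is rejected", {
  expect_error(coverage_map(list(dilated_conv_spec(3, 2)), grid_size = 3),
               "smaller than the receptive field")
})

test_that("conv spec validation rejects even kernels and bad rates", {
  expect_error(dilated_conv_spec(kernel = 4), "odd")
  expect_error(dilated_conv_spec(rate = 0), "positive")
})
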