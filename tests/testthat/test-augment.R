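aug_scene <- function(seed = 5) {
  generate_scene(scene_spec(48, 48, n_nuclei = 6, mode = "fluorescence",
                            radius_range = c(3, 5), min_instance_area = 9,
                            seed = seed))
}

record_of <- function(...) {
  structure(list(seed = 1L, steps = list(...)), class = "augmentation_record")
}
step_of <- function(name, ...) list(name = name, params = list(...))

test_that("a fixed seed reproduces outputs and records bitwise", {
  sc <- aug_scene()
  a <- random_augment(sc$image, sc$labels, seed = 11)
  b <- random_augment(sc$image, sc$labels, seed = 11)
  expect_identical(a, b)
  c_ <- random_augment(sc$image, sc$labels, seed = 12)
  expect_false(identical(a$record, c_$record))
})

test_that("replaying a record on the original input reproduces the output", {
  sc <- aug_scene(7)
  for (seed in c(1, 2, 3, 4)) {
    a <- suppressWarnings(random_augment(sc$image, sc$labels, seed = seed))
    r <- suppressWarnings(replay(sc$image, sc$labels, a$record))
    expect_identical(r$image, a$image)
    expect_identical(r$labels, a$labels)
  }
})

test_that("horizontal flip maps (r, c) to (r, W - 1 - c) on both members", {
  sc <- aug_scene(3)
  W <- ncol(sc$labels)
  out <- replay(sc$image, sc$labels,
                record_of(step_of("flip", direction = "horizontal")))
  for (px in list(c(5, 7), c(20, 33), c(48, 1))) {
    expect_equal(out$labels[px[1], W - px[2] + 1], sc$labels[px[1], px[2]])
    expect_equal(out$image[px[1], W - px[2] + 1, ], sc$image[px[1], px[2], ])
  }
  again <- replay(out$image, out$labels,
                  record_of(step_of("flip", direction = "horizontal")))
  expect_identical(again$labels, sc$labels)   # involution
  expect_identical(again$image, sc$image)
})

test_that("an empty record is the identity", {
  sc <- aug_scene(9)
  out <- replay(sc$image, sc$labels, record_of())
  expect_identical(out$image, sc$image)
  expect_identical(out$labels, sc$labels)
})

test_that("a quarter rotation moves a corner instance to the rotated corner", {
  lab <- matrix(0L, 9, 9); lab[1, 1] <- 1L
  img <- array(0L, c(9, 9, 3))
  out <- replay(img, lab, record_of(step_of("rotate", k = 1L)))
  # counterclockwise: top-left corner lands on the bottom-left corner
  expect_equal(which(out$labels == 1L, arr.ind = TRUE)[1, ], c(row = 9, col = 1))
  full <- replay(img, lab, record_of(step_of("rotate", k = 4L)))
  expect_identical(full$labels, lab)
})

test_that("photometric transforms leave labels bitwise unchanged", {
  sc <- aug_scene(13)
  for (st in list(step_of("sharpen", amount = 1.2),
                  step_of("gauss_noise", sd = 0.03, subseed = 99L),
                  step_of("grayscale"),
                  step_of("contrast_brightness", alpha = 1.1, beta = -0.05),
                  step_of("channel_shuffle", perm = c(3L, 1L, 2L)))) {
    out <- replay(sc$image, sc$labels, record_of(st))
    expect_identical(out$labels, sc$labels)
  }
})

test_that("instances fully inside the frame survive flips and quarter turns", {
  sc <- aug_scene(15)
  ids <- sort(unique(sc$labels[sc$labels > 0]))
  for (st in list(step_of("flip", direction = "vertical"),
                  step_of("rotate", k = 2L))) {
    out <- replay(sc$image, sc$labels, record_of(st))
    expect_identical(sort(unique(out$labels[out$labels > 0])), ids)
    expect_identical(sort(tabulate(out$labels)), sort(tabulate(sc$labels)))
  }
})

test_that("severe downscaling drops vanished instances with a warning", {
  lab <- matrix(0L, 32, 32); lab[1:2, 1:2] <- 1L; lab[16:20, 16:20] <- 2L
  img <- array(100L, c(32, 32, 3))
  expect_warning(out <- replay(img, lab, record_of(step_of("scale", factor = 0.2))),
                 "dropped")
  expect_false(1L %in% out$labels)
})

test_that("records serialize to text and replay identically after reading", {
  sc <- aug_scene(21)
  a <- suppressWarnings(random_augment(sc$image, sc$labels, seed = 31))
  f <- withr::local_tempfile(fileext = ".json")
  write_augmentation_record(a$record, f)
  rec <- read_augmentation_record(f)
  out <- suppressWarnings(replay(sc$image, sc$labels, rec))
  expect_identical(out$image, a$image)
  expect_identical(out$labels, a$labels)
})

test_that("unknown transform names are rejected", {
  sc <- aug_scene(2)
  expect_error(replay(sc$image, sc$labels, record_of(step_of("solarize"))),
               "unknown transform")
})
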