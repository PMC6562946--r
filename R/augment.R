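# Stochastic paired augmentation with replayable records.
#
# Eight transform families: sharpening, Gaussian noise, grayscale
# conversion, contrast/brightness, random scaling, rotation, flip, channel
# rearrangement.  A random subset (1-3 draws) is composed per call.
# Geometric transforms are applied identically to the label map with
# nearest-neighbour interpolation; photometric transforms never touch the
# labels.  Every call returns a record of the drawn transforms and their
# parameters, and replaying a record on the same input reproduces the output
# bitwise (noise is regenerated from a recorded sub-seed).

AUG_TRANSFORMS <- c("sharpen", "gauss_noise", "grayscale",
                    "contrast_brightness", "scale", "rotate", "flip",
                    "channel_shuffle")

img_to_unit <- function(img) img / 255
unit_to_img <- function(x) {
  array(as.integer(round(clamp(x, 0, 1) * 255)), dim(x))
}

# 3x3 box blur with edge replication, per channel
box_blur3 <- function(x) {
  H <- dim(x)[1]; W <- dim(x)[2]
  ri <- function(i) clamp(seq_len(H) + i, 1, H)
  ci <- function(j) clamp(seq_len(W) + j, 1, W)
  out <- array(0, dim(x))
  for (i in -1:1) for (j in -1:1) out <- out + x[ri(i), ci(j), , drop = FALSE]
  out / 9
}

bilinear_sample_plane <- function(plane, xs, ys) {
  H <- nrow(plane); W <- ncol(plane)
  u <- clamp(xs - 0.5, 0, W - 1); v <- clamp(ys - 0.5, 0, H - 1)
  c0 <- pmin(floor(u), W - 2); r0 <- pmin(floor(v), H - 2)
  fu <- u - c0; fv <- v - r0
  idx <- function(r, cc) plane[cbind(as.vector(r) + 1L, as.vector(cc) + 1L)]
  out <- (1 - fv) * (1 - fu) * idx(r0, c0) + fv * (1 - fu) * idx(r0 + 1, c0) +
         (1 - fv) * fu * idx(r0, c0 + 1) + fv * fu * idx(r0 + 1, c0 + 1)
  matrix(out, H, W)
}

nn_sample_labels <- function(labels, xs, ys) {
  H <- nrow(labels); W <- ncol(labels)
  cc <- round(xs + 0.5); rr <- round(ys + 0.5)
  ok <- cc >= 1 & cc <= W & rr >= 1 & rr <= H
  out <- matrix(0L, H, W)
  out[ok] <- labels[cbind(rr[ok], cc[ok])]
  out
}

# inverse-mapped affine warp about the image center
warp_pair <- function(image, labels, inv_map) {
  H <- dim(image)[1]; W <- dim(image)[2]
  xs <- matrix(rep(seq_len(W) - 0.5, each = H), H, W)  # 0-based pixel centers
  ys <- matrix(rep(seq_len(H) - 0.5, W), H, W)
  src <- inv_map(xs, ys)
  img <- array(0, dim(image))
  for (ch in seq_len(dim(image)[3]))
    img[, , ch] <- bilinear_sample_plane(image[, , ch], src$x, src$y)
  list(image = img, labels = nn_sample_labels(labels, src$x, src$y))
}

apply_one_transform <- function(image, labels, name, params) {
  H <- dim(image)[1]; W <- dim(image)[2]
  switch(name,
    sharpen = {
      u <- img_to_unit(image)
      u <- u + params$amount * (u - box_blur3(u))
      list(image = unit_to_img(u), labels = labels)
    },
    gauss_noise = {
      u <- img_to_unit(image)
      noise <- with_seed(params$subseed,
                         array(stats::rnorm(length(u), 0, params$sd), dim(u)))
      list(image = unit_to_img(u + noise), labels = labels)
    },
    grayscale = {
      u <- img_to_unit(image)
      g <- 0.299 * u[, , 1] + 0.587 * u[, , 2] + 0.114 * u[, , 3]
      list(image = unit_to_img(array(rep(g, 3), dim(u))), labels = labels)
    },
    contrast_brightness = {
      u <- img_to_unit(image)
      list(image = unit_to_img(params$alpha * (u - 0.5) + 0.5 + params$beta),
           labels = labels)
    },
    scale = {
      f <- params$factor
      cx <- W / 2; cy <- H / 2
      out <- warp_pair(image, labels, function(xs, ys)
        list(x = cx + (xs - cx) / f, y = cy + (ys - cy) / f))
      list(image = unit_to_img(img_to_unit(out$image)), labels = out$labels)
    },
    rotate = {
      if (!is.null(params$k)) {   # multiples of 90 degrees, exact index ops
        img <- image; lab <- labels
        for (i in seq_len(params$k)) {
          # 90 degrees counterclockwise: (r, c) -> (H' - c + 1, r)
          img <- aperm(img, c(2, 1, 3))[rev(seq_len(dim(img)[2])), , , drop = FALSE]
          lab <- t(lab)[rev(seq_len(ncol(lab))), , drop = FALSE]
        }
        list(image = img, labels = lab)
      } else {
        th <- params$angle * pi / 180
        cx <- W / 2; cy <- H / 2
        out <- warp_pair(image, labels, function(xs, ys) {
          dx <- xs - cx; dy <- ys - cy
          list(x = cx + cos(th) * dx + sin(th) * dy,
               y = cy - sin(th) * dx + cos(th) * dy)
        })
        list(image = unit_to_img(img_to_unit(out$image)), labels = out$labels)
      }
    },
    flip = {
      if (params$direction == "horizontal") {
        list(image = image[, rev(seq_len(W)), , drop = FALSE],
             labels = labels[, rev(seq_len(W)), drop = FALSE])
      } else {
        list(image = image[rev(seq_len(H)), , , drop = FALSE],
             labels = labels[rev(seq_len(H)), , drop = FALSE])
      }
    },
    channel_shuffle = {
      list(image = image[, , params$perm, drop = FALSE], labels = labels)
    },
    stopf("unknown transform '%s'", name))
}

draw_params <- function(name, small_angle = FALSE) {
  switch(name,
    sharpen = list(amount = stats::runif(1, 0.5, 1.5)),
    gauss_noise = list(sd = stats::runif(1, 0.01, 0.05),
                       subseed = sample.int(2147483646L, 1)),
    grayscale = list(),
    contrast_brightness = list(alpha = stats::runif(1, 0.7, 1.3),
                               beta = stats::runif(1, -0.15, 0.15)),
    scale = list(factor = stats::runif(1, 0.75, 1.3)),
    rotate = if (small_angle) list(angle = stats::runif(1, -15, 15))
             else list(k = sample(1:3, 1)),
    flip = list(direction = sample(c("horizontal", "vertical"), 1)),
    channel_shuffle = list(perm = sample(3L)))
}

check_dropped_instances <- function(before, after) {
  lost <- setdiff(unique(before[before > 0]), unique(after[after > 0]))
  if (length(lost) > 0L)
    warnf("augmentation dropped %d instance(s) reduced to 0 px: %s",
          length(lost), paste(lost, collapse = ", "))
}

#' Randomly augment an image/label pair
#'
#' Draws 1-3 transforms (uniformly, without replacement) from the eight
#' supported families, composes them in the drawn order, and returns the
#' transformed pair together with a replayable record. Identical seeds
#' reproduce identical outputs and records. Instances scaled/rotated out of
#' the frame (0 px left) are dropped with a warning.
#'
#' @param image (H, W, 3) integer image, 0..255.
#' @param labels integer label map of the same spatial size.
#' @param seed integer seed.
#' @param n_transforms optional fixed number of transforms (1-8).
#' @param transforms candidate transform names (default all eight).
#' @param small_angle draw continuous rotation angles (reflection-free
#'   nearest/bilinear warp) instead of multiples of 90 degrees.
#' @return List with `image`, `labels` and `record` (class
#'   `augmentation_record`).
#' @export
random_augment <- function(image, labels, seed, n_transforms = NULL,
                           transforms = AUG_TRANSFORMS, small_angle = FALSE) {
  if (!all(dim(image)[1:2] == dim(labels)))
    stopf("image and labels must share spatial size")
  with_seed(seed, {
    n <- n_transforms %||% sample(1:3, 1)
    chosen <- sample(transforms, n)
    steps <- lapply(chosen, function(nm)
      list(name = nm, params = draw_params(nm, small_angle)))
    record <- structure(list(seed = as.integer(seed), steps = steps),
                        class = "augmentation_record")
    out <- replay(image, labels, record)
    list(image = out$image, labels = out$labels, record = record)
  })
}

#' Replay an augmentation record
#'
#' Re-applies the recorded transform sequence with its stored parameters.
#' Deterministic: replaying on the original input reproduces the recorded
#' augmentation bitwise (annotation stays consistent with the image).
#'
#' @param image,labels input pair (see [random_augment()]).
#' @param record an `augmentation_record`.
#' @return List with `image` and `labels`.
#' @export
replay <- function(image, labels, record) {
  stopifnot(inherits(record, "augmentation_record"))
  before <- labels
  for (st in record$steps) {
    out <- apply_one_transform(image, labels, st$name, st$params)
    image <- out$image; labels <- out$labels
  }
  check_dropped_instances(before, labels)
  list(image = image, labels = labels)
}

#' @export
print.augmentation_record <- function(x, ...) {
  cat("augmentation_record:",
      paste(vapply(x$steps, `[[`, character(1), "name"), collapse = " -> "),
      "\n")
  invisible(x)
}

#' Serialize an augmentation record as JSON text
#'
#' @param record an `augmentation_record`.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_augmentation_record <- function(record, path) {
  jsonlite::write_json(unclass(record), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an augmentation record written by [write_augmentation_record()]
#'
#' @param path JSON file.
#' @return An `augmentation_record`.
#' @export
read_augmentation_record <- function(path) {
  r <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  r$steps <- lapply(r$steps, function(st) {
    if (!is.null(st$params$subseed)) st$params$subseed <- as.integer(st$params$subseed)
    if (!is.null(st$params$k)) st$params$k <- as.integer(st$params$k)
    if (!is.null(st$params$perm)) st$params$perm <- as.integer(st$params$perm)
    st
  })
  structure(r, class = "augmentation_record")
}
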