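# Detection heads: ROI-align pooling, the softmax classification math
# (hypothesis, cost, gradient, SGD update), the mask branch, and the
# multi-task total.

## ---- ROI align -------------------------------------------------------------

# sparse bilinear-sampling matrix for one box: (S*S, H*W), rows in
# column-major output order, 4 regularly spaced sample points per bin
# averaged, no coordinate rounding
roi_align_matrix <- function(H, W, box, out_size, spatial_scale = 1,
                             sampling = 2L) {
  x1 <- box[1] * spatial_scale; y1 <- box[2] * spatial_scale
  x2 <- box[3] * spatial_scale; y2 <- box[4] * spatial_scale
  w <- x2 - x1; h <- y2 - y1
  if (w <= 0 || h <= 0) stopf("degenerate box (width/height <= 0)")
  S <- out_size
  bw <- w / S; bh <- h / S
  frac <- (seq_len(sampling) - 0.5) / sampling
  # sample coords per output cell (by, bx), column-major
  bx <- rep(seq_len(S), each = S); by <- rep(seq_len(S), S)
  xs <- outer(x1 + (bx - 1) * bw, frac * bw, "+")      # (S*S, sampling)
  ys <- outer(y1 + (by - 1) * bh, frac * bh, "+")
  n_pts <- sampling * sampling
  rows <- integer(0); cols <- integer(0); vals <- numeric(0)
  for (i in seq_len(sampling)) for (j in seq_len(sampling)) {
    u <- clamp(xs[, i] - 0.5, 0, W - 1)   # continuous cell-index coords
    v <- clamp(ys[, j] - 0.5, 0, H - 1)
    c0 <- pmin(floor(u), W - 2); r0 <- pmin(floor(v), H - 2)
    fx <- u - c0; fy <- v - r0
    base <- function(r, cc) (r + 1) + cc * H   # 1-based flat index of (row r, col cc), 0-based inputs
    idx <- seq_len(S * S)
    rows <- c(rows, rep(idx, 4))
    cols <- c(cols, base(r0, c0), base(r0 + 1, c0), base(r0, c0 + 1),
              base(r0 + 1, c0 + 1))
    vals <- c(vals, (1 - fy) * (1 - fx), fy * (1 - fx), (1 - fy) * fx, fy * fx)
  }
  Matrix::sparseMatrix(i = rows, j = cols, x = vals / n_pts,
                       dims = c(S * S, H * W))
}

#' ROI-align pooling
#'
#' Pools a proposal's features to a fixed `out_size` x `out_size` grid by
#' bilinear sampling at 4 regularly spaced sub-bin points per output cell
#' (averaged), without any coordinate rounding. The output size is
#' independent of the box size, and the operation is linear in the feature
#' map.
#'
#' @param features (H, W, C) feature array.
#' @param boxes a single box `c(x1, y1, x2, y2)` or an n x 4 matrix, in image
#'   coordinates (half-open).
#' @param out_size output grid side length (default 7).
#' @param spatial_scale factor mapping image coordinates to the feature grid
#'   (1/stride; default 1).
#' @return (S, S, C) array for a single box; a list of such arrays for a
#'   matrix of boxes.
#' @export
roi_align <- function(features, boxes, out_size = 7L, spatial_scale = 1) {
  d <- dim(features)
  fm <- matrix(features, d[1] * d[2], d[3])
  one <- function(b) {
    P <- roi_align_matrix(d[1], d[2], b, out_size, spatial_scale)
    array(as.matrix(P %*% fm), c(out_size, out_size, d[3]))
  }
  if (is.null(dim(boxes))) return(one(boxes))
  lapply(seq_len(nrow(boxes)), function(i) one(boxes[i, ]))
}

# autodiff ROI align: list of pooled (S, S, C) nodes for a box matrix
ag_roi_align <- function(x, boxes, out_size, spatial_scale = 1) {
  d <- dim(ag_value(x))
  xm <- ag_reshape(x, c(d[1] * d[2], d[3]))
  lapply(seq_len(nrow(boxes)), function(i) {
    P <- roi_align_matrix(d[1], d[2], boxes[i, ], out_size, spatial_scale)
    ag_reshape(ag_sparse_mm(P, xm), c(out_size, out_size, d[3]))
  })
}

## ---- softmax regression math ----------------------------------------------

#' Softmax classifier parameters
#'
#' @param theta k x d matrix of per-class weight vectors (k >= 2 classes,
#'   d features).
#' @param alpha learning rate used by [sgd_step()].
#' @return Object of class `softmax_params`.
#' @export
softmax_params <- function(theta, alpha = 0.1) {
  theta <- as.matrix(theta)
  if (nrow(theta) < 2L) stopf("softmax needs k >= 2 classes")
  structure(list(theta = theta, k = nrow(theta), alpha = alpha),
            class = "softmax_params")
}

#' Class probabilities of the softmax hypothesis
#'
#' `p_i = exp(theta_i' x) / sum_k exp(theta_k' x)`, computed with
#' max-subtraction for numerical stability; probabilities sum to 1. Adding a
#' constant to every logit leaves the result unchanged (shift invariance).
#'
#' @param x feature vector (length d) or n x d matrix of feature rows.
#' @param params a [softmax_params()].
#' @return Probability vector (length k) or n x k matrix.
#' @export
softmax_probs <- function(x, params) {
  stopifnot(inherits(params, "softmax_params"))
  single <- is.null(dim(x))
  xm <- if (single) matrix(x, 1) else as.matrix(x)
  z <- xm %*% t(params$theta)
  z <- z - apply(z, 1, max)
  e <- exp(z)
  p <- e / rowSums(e)
  if (single) p[1, ] else p
}

#' Softmax cross-entropy cost
#'
#' `J(theta) = -(1/m) sum_i sum_j 1{y_i = j} (theta_j' x_i -
#' log sum_l exp(theta_l' x_i))`.
#'
#' @param batch list with `x` (m x d feature matrix) and `y` (labels in
#'   1..k).
#' @param params a [softmax_params()].
#' @return Scalar cost.
#' @export
softmax_loss <- function(batch, params) {
  xm <- as.matrix(batch$x)
  if (nrow(xm) == 0L) stopf("empty batch")
  if (any(batch$y < 1L | batch$y > params$k)) stopf("labels must lie in 1..k")
  p <- softmax_probs(xm, params)
  -mean(log(pmax(p[cbind(seq_len(nrow(xm)), batch$y)], 1e-12)))
}

#' Gradient of the softmax cost
#'
#' `dJ/dtheta_j = -(1/m) sum_i (1{y_i = j} - p(y_i = j | x_i)) x_i`.
#' The per-sample contributions summed over classes vanish, since
#' probabilities sum to one.
#'
#' @inheritParams softmax_loss
#' @return k x d gradient matrix (rows align with `params$theta`).
#' @export
softmax_gradient <- function(batch, params) {
  xm <- as.matrix(batch$x)
  m <- nrow(xm)
  if (m == 0L) stopf("empty batch")
  p <- softmax_probs(xm, params)
  ind <- matrix(0, m, params$k)
  ind[cbind(seq_len(m), batch$y)] <- 1
  -crossprod(ind - p, xm) / m
}

#' One (stochastic) gradient-descent update
#'
#' `theta_j <- theta_j - alpha * dJ/dtheta_j` for every class j.
#'
#' @param params a [softmax_params()].
#' @param gradient k x d gradient matrix.
#' @param alpha step size; defaults to `params$alpha`.
#' @return Updated `softmax_params`.
#' @export
sgd_step <- function(params, gradient, alpha = NULL) {
  stopifnot(inherits(params, "softmax_params"))
  alpha <- alpha %||% params$alpha
  if (alpha <= 0) stopf("`alpha` must be positive")
  params$theta <- params$theta - alpha * gradient
  params
}

## ---- mask branch ------------------------------------------------------------

#' Build the mask prediction head
#'
#' A small fully convolutional stack over the pooled ROI feature: `n_conv`
#' 3x3 convolutions, a 2x upsampling step realized as nearest-neighbour
#' expansion followed by a 3x3 convolution, and a final 1x1 convolution to
#' per-class mask logits. A 14x14 pooled input yields 28x28 logits.
#'
#' @param in_channels pooled feature channels.
#' @param channels hidden width (default 64).
#' @param num_classes foreground classes (default 1: nucleus).
#' @param n_conv number of leading 3x3 convolutions (default 2).
#' @param init `"he"` or `"zero"`.
#' @return Object of class `mask_head`.
#' @export
build_mask_head <- function(in_channels, channels = 64L, num_classes = 1L,
                            n_conv = 2L, init = "he") {
  convs <- list()
  cur <- in_channels
  for (i in seq_len(n_conv)) {
    convs[[i]] <- new_conv_layer(3L, cur, channels, init = init)
    cur <- channels
  }
  up_conv <- new_conv_layer(3L, cur, channels, init = init)
  out_conv <- new_conv_layer(1L, channels, num_classes, init = init)
  structure(list(convs = convs, up_conv = up_conv, out_conv = out_conv,
                 num_classes = as.integer(num_classes)),
            class = "mask_head")
}

# node-in/node-out forward
mask_head_forward <- function(head, roi) {
  h <- if (ag_is_node(roi)) roi else ag_node(roi)
  for (l in head$convs) h <- ag_relu(conv_fwd(l, h))
  h <- ag_relu(conv_fwd(head$up_conv, ag_upsample2(h)))
  conv_fwd(head$out_conv, h)
}

#' Per-class mask logits for a pooled ROI feature
#'
#' @param head a [build_mask_head()] result.
#' @param roi pooled (S, S, C) feature array.
#' @return (2S, 2S, num_classes) array of mask logits; apply a sigmoid for
#'   probabilities.
#' @export
mask_head_logits <- function(head, roi) {
  stopifnot(inherits(head, "mask_head"))
  ag_value(mask_head_forward(head, roi))
}

#' Paste a predicted ROI mask into image coordinates
#'
#' Resizes the M x M mask probabilities to the box size by bilinear
#' interpolation and thresholds them into a binary mask covering the
#' (rounded) box region of an H x W canvas.
#'
#' @param probs M x M matrix of mask probabilities.
#' @param box target box `c(x1, y1, x2, y2)` in image coordinates.
#' @param height,width canvas size.
#' @param threshold binarization threshold (default 0.5).
#' @return H x W logical matrix.
#' @export
paste_mask <- function(probs, box, height, width, threshold = 0.5) {
  M <- nrow(probs)
  x0 <- max(0L, round(box[1])); x1 <- min(width, round(box[3]))
  y0 <- max(0L, round(box[2])); y1 <- min(height, round(box[4]))
  out <- matrix(FALSE, height, width)
  if (x1 <= x0 || y1 <= y0) return(out)
  w <- box[3] - box[1]; h <- box[4] - box[2]
  cols <- (x0 + 1):x1; rows <- (y0 + 1):y1
  # sample mask at pixel centers, mask cell centers at (i - 0.5) * cell
  u <- clamp((cols - 0.5 - box[1]) / w * M - 0.5, 0, M - 1)
  v <- clamp((rows - 0.5 - box[2]) / h * M - 0.5, 0, M - 1)
  c0 <- pmin(floor(u), M - 2); r0 <- pmin(floor(v), M - 2)
  fu <- u - c0; fv <- v - r0
  vals <- outer(1 - fv, 1 - fu) * matrix(probs[cbind(rep(r0 + 1, length(c0)), rep(c0 + 1, each = length(r0)))], length(rows)) +
          outer(fv, 1 - fu)     * matrix(probs[cbind(rep(r0 + 2, length(c0)), rep(c0 + 1, each = length(r0)))], length(rows)) +
          outer(1 - fv, fu)     * matrix(probs[cbind(rep(r0 + 1, length(c0)), rep(c0 + 2, each = length(r0)))], length(rows)) +
          outer(fv, fu)         * matrix(probs[cbind(rep(r0 + 2, length(c0)), rep(c0 + 2, each = length(r0)))], length(rows))
  out[rows, cols] <- vals >= threshold
  out
}

## ---- multi-task total -------------------------------------------------------

#' Multi-task detection loss
#'
#' Sum of the region-proposal, classification, box-regression and mask terms
#' (unweighted by default; weights configurable). The value carries the
#' individual components as an attribute for logging.
#'
#' @param rpn_terms an `rpn_loss_terms` object (its `total` is used) or a
#'   number.
#' @param cls_loss,box_loss,mask_loss scalar head losses.
#' @param weights length-4 weights for (rpn, cls, box, mask).
#' @return Scalar total with attribute `components`.
#' @export
multi_task_loss <- function(rpn_terms, cls_loss, box_loss, mask_loss,
                            weights = c(1, 1, 1, 1)) {
  rpn <- if (inherits(rpn_terms, "rpn_loss_terms")) rpn_terms$total else rpn_terms
  comp <- c(rpn = rpn, cls = cls_loss, box = box_loss, mask = mask_loss)
  if (any(!is.finite(comp))) stopf("non-finite loss component")
  structure(sum(weights * comp), components = comp)
}
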