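# Region-proposal machinery: anchor generation, box parameterization,
# anchor/ground-truth assignment, the two-term RPN objective, and greedy
# non-maximum suppression.
#
# Boxes are rows of (x1, y1, x2, y2) in 0-based half-open pixel coordinates;
# x runs along image columns, y along rows.

boxes_to_cwh <- function(b) {
  cbind(x = (b[, 1] + b[, 3]) / 2, y = (b[, 2] + b[, 4]) / 2,
        w = b[, 3] - b[, 1], h = b[, 4] - b[, 2])
}

cwh_to_boxes <- function(c4) {
  cbind(c4[, 1] - c4[, 3] / 2, c4[, 2] - c4[, 4] / 2,
        c4[, 1] + c4[, 3] / 2, c4[, 2] + c4[, 4] / 2)
}

as_box_matrix <- function(b) {
  if (is.null(dim(b))) b <- matrix(b, ncol = 4, byrow = FALSE)
  if (ncol(b) != 4) stopf("boxes must have 4 columns (x1, y1, x2, y2)")
  b
}

#' Pairwise intersection-over-union of two box sets
#'
#' @param a,b box matrices (n x 4 and m x 4, half-open coordinates).
#' @return n x m matrix of IoU values.
#' @export
box_iou <- function(a, b) {
  a <- as_box_matrix(a); b <- as_box_matrix(b)
  n <- nrow(a); m <- nrow(b)
  ix <- pmax(0, outer(a[, 3], b[, 3], pmin) - outer(a[, 1], b[, 1], pmax))
  iy <- pmax(0, outer(a[, 4], b[, 4], pmin) - outer(a[, 2], b[, 2], pmax))
  inter <- ix * iy
  area_a <- (a[, 3] - a[, 1]) * (a[, 4] - a[, 2])
  area_b <- (b[, 3] - b[, 1]) * (b[, 4] - b[, 2])
  inter / (outer(area_a, area_b, "+") - inter)
}

#' Generate anchor boxes over feature-grid locations
#'
#' For every location, one anchor per (scale, ratio) combination is centered
#' on the location mapped to image coordinates. A scale `s` fixes the anchor
#' area at `s^2` regardless of aspect ratio: width `s/sqrt(ratio)`, height
#' `s*sqrt(ratio)` (ratio = height/width), so three scales and three ratios
#' yield nine anchors per location.
#'
#' @param scales base sizes in pixels (the default 8/16/32 spans the small
#'   nucleus areas of dense microscopy scenes).
#' @param ratios aspect ratios height/width (default 0.5, 1, 2).
#' @param locations either a 2-column matrix of (row, col) feature-grid
#'   positions (1-based) or a length-2 integer `c(h, w)` meaning the full
#'   h x w grid in column-major order.
#' @param stride feature-grid stride in pixels.
#' @param order `"location"` groups the anchors of one location together;
#'   `"anchor"` groups all locations of one (scale, ratio) combination
#'   together (the layout of channel-stacked network predictions).
#' @return n x 4 anchor box matrix.
#' @export
generate_anchors <- function(scales = c(8, 16, 32), ratios = c(0.5, 1, 2),
                             locations = c(1L, 1L), stride = 8,
                             order = c("location", "anchor")) {
  order <- match.arg(order)
  if (length(scales) == 0L || any(scales <= 0)) stopf("scales must be positive")
  if (length(ratios) == 0L || any(ratios <= 0)) stopf("ratios must be positive")
  if (is.null(dim(locations))) {
    stopifnot(length(locations) == 2L)
    h <- locations[1]; w <- locations[2]
    locations <- cbind(rep(seq_len(h), w), rep(seq_len(w), each = h))
  }
  cx <- (locations[, 2] - 0.5) * stride
  cy <- (locations[, 1] - 0.5) * stride
  shapes <- expand.grid(ratio = ratios, scale = scales)  # ratio varies fastest
  ws <- shapes$scale / sqrt(shapes$ratio)
  hs <- shapes$scale * sqrt(shapes$ratio)
  nl <- nrow(locations); na <- nrow(shapes)
  if (order == "location") {
    cx <- rep(cx, each = na); cy <- rep(cy, each = na)
    ws <- rep(ws, nl); hs <- rep(hs, nl)
  } else {
    cx <- rep(cx, na); cy <- rep(cy, na)
    ws <- rep(ws, each = nl); hs <- rep(hs, each = nl)
  }
  cbind(cx - ws / 2, cy - hs / 2, cx + ws / 2, cy + hs / 2)
}

#' Parameterize boxes against anchors
#'
#' Encodes each box relative to its anchor as dimensionless regression
#' targets: `tx = (x - xa)/wa`, `ty = (y - ya)/ha`, `tw = log(w/wa)`,
#' `th = log(h/ha)`, where (x, y, w, h) are box center and size.
#'
#' @param boxes,anchors box matrices of equal row count (or single boxes as
#'   length-4 vectors).
#' @return n x 4 matrix of (tx, ty, tw, th).
#' @export
encode_boxes <- function(boxes, anchors) {
  b <- boxes_to_cwh(as_box_matrix(boxes))
  a <- boxes_to_cwh(as_box_matrix(anchors))
  if (any(a[, 3] <= 0) || any(a[, 4] <= 0)) stopf("degenerate anchor (w or h <= 0)")
  cbind(tx = (b[, 1] - a[, 1]) / a[, 3],
        ty = (b[, 2] - a[, 2]) / a[, 4],
        tw = log(b[, 3] / a[, 3]),
        th = log(b[, 4] / a[, 4]))
}

#' Invert the box parameterization
#'
#' Exact algebraic inverse of [encode_boxes()]. Log-size deltas are clamped to
#' `log(1000/16)` before exponentiation (with a warning) to avoid overflow on
#' wild predictions; decoded boxes are clipped to `clip_to = c(W, H)` image
#' bounds only when supplied.
#'
#' @param deltas n x 4 matrix of (tx, ty, tw, th).
#' @param anchors n x 4 anchor boxes.
#' @param clip_to optional `c(width, height)` image bounds.
#' @return n x 4 decoded box matrix.
#' @export
decode_boxes <- function(deltas, anchors, clip_to = NULL) {
  d <- as_box_matrix(deltas)
  if (any(!is.finite(d))) stopf("deltas must be finite")
  a <- boxes_to_cwh(as_box_matrix(anchors))
  lim <- log(1000 / 16)
  if (any(d[, 3:4] > lim)) {
    warnf("clamping %d oversized log-scale deltas", sum(d[, 3:4] > lim))
    d[, 3] <- pmin(d[, 3], lim); d[, 4] <- pmin(d[, 4], lim)
  }
  out <- cwh_to_boxes(cbind(a[, 1] + d[, 1] * a[, 3],
                            a[, 2] + d[, 2] * a[, 4],
                            a[, 3] * exp(d[, 3]),
                            a[, 4] * exp(d[, 4])))
  if (!is.null(clip_to)) {
    out[, c(1, 3)] <- clamp(out[, c(1, 3)], 0, clip_to[1])
    out[, c(2, 4)] <- clamp(out[, c(2, 4)], 0, clip_to[2])
  }
  out
}

#' Smooth-L1 (Huber) penalty
#'
#' `0.5 x^2` for `|x| <= 1`, `|x| - 0.5` otherwise; applied elementwise. The
#' two pieces agree at `|x| = 1`, so the function is continuous, and it
#' matches L2/2 inside the unit interval while growing only linearly outside,
#' making the box-regression loss robust to outliers.
#'
#' @param x numeric vector/matrix of residuals.
#' @return Elementwise penalty, same shape as `x`.
#' @examples
#' smooth_l1(c(0, 1, -3))  # 0, 0.5, 2.5
#' @export
smooth_l1 <- function(x) {
  a <- abs(x)
  ifelse(a <= 1, 0.5 * x^2, a - 0.5)
}

#' Label anchors against ground-truth boxes
#'
#' An anchor is positive when its best IoU reaches `iou_hi` or when it is the
#' best-overlapping anchor for some ground-truth box (the rescue rule, which
#' guarantees every ground truth with at least one overlapping anchor gets a
#' positive); negative when its best IoU is below `iou_lo`; ignored otherwise.
#'
#' @param anchors n x 4 anchor boxes.
#' @param gt_boxes m x 4 ground-truth boxes (may have zero rows).
#' @param iou_hi,iou_lo positive/negative IoU thresholds (defaults 0.7/0.3).
#' @return List with `label` (character: positive/negative/ignore),
#'   `gt_index` (matched ground-truth row for positives, NA otherwise) and
#'   `max_iou`.
#' @export
assign_anchors <- function(anchors, gt_boxes, iou_hi = 0.7, iou_lo = 0.3) {
  if (iou_lo > iou_hi) stopf("iou_lo must not exceed iou_hi")
  anchors <- as_box_matrix(anchors)
  n <- nrow(anchors)
  if (is.null(gt_boxes) || NROW(gt_boxes) == 0L) {
    return(list(label = rep("negative", n), gt_index = rep(NA_integer_, n),
                max_iou = rep(0, n)))
  }
  iou <- box_iou(anchors, gt_boxes)
  max_iou <- apply(iou, 1, max)
  gt_index <- apply(iou, 1, which.max)
  label <- rep("ignore", n)
  label[max_iou < iou_lo] <- "negative"
  label[max_iou >= iou_hi] <- "positive"
  # rescue: best anchor(s) per ground truth become positive
  for (j in seq_len(ncol(iou))) {
    best <- max(iou[, j])
    if (best > 0) {
      hit <- which(iou[, j] >= best - 1e-9)
      label[hit] <- "positive"
      gt_index[hit] <- j
    }
  }
  gt_index[label != "positive"] <- NA_integer_
  list(label = label, gt_index = gt_index, max_iou = max_iou)
}

#' Two-term RPN objective
#'
#' `L = (1/Ncls) * sum Lcls(p, p*) + lambda * (1/Nreg) * sum p* Lreg(t, t*)`:
#' binary log loss over labeled (non-ignored) anchors plus smooth-L1 box
#' regression over positive anchors only (the `p*` gate). Ignored anchors
#' contribute to neither term.
#'
#' @param p predicted objectness probabilities, length n, in `[0, 1]`.
#' @param assignment anchor labels from [assign_anchors()].
#' @param t_pred,t_star n x 4 predicted and target box deltas (rows of
#'   non-positive anchors are ignored).
#' @param lambda balance weight between the terms (default 1).
#' @param n_cls,n_reg normalizers; default to the labeled-anchor count and
#'   the positive count (floored at 1).
#' @return Object of class `rpn_loss_terms`: list with `total`, `cls_term`,
#'   `reg_term`, `n_cls`, `n_reg`, `lambda`.
#' @export
rpn_loss <- function(p, assignment, t_pred, t_star, lambda = 1,
                     n_cls = NULL, n_reg = NULL) {
  lab <- assignment$label
  use <- lab != "ignore"
  pos <- lab == "positive"
  pstar <- as.numeric(pos)
  pc <- clamp(p, 1e-7, 1 - 1e-7)
  n_cls <- n_cls %||% max(1L, sum(use))
  n_reg <- n_reg %||% max(1L, sum(pos))
  cls <- sum(-(pstar[use] * log(pc[use]) + (1 - pstar[use]) * log(1 - pc[use]))) / n_cls
  reg <- 0
  if (any(pos)) {
    t_pred <- as_box_matrix(t_pred); t_star <- as_box_matrix(t_star)
    reg <- sum(smooth_l1(t_pred[pos, , drop = FALSE] -
                         t_star[pos, , drop = FALSE])) / n_reg
  }
  structure(list(total = cls + lambda * reg, cls_term = cls, reg_term = reg,
                 n_cls = n_cls, n_reg = n_reg, lambda = lambda),
            class = "rpn_loss_terms")
}

#' @export
print.rpn_loss_terms <- function(x, ...) {
  cat(sprintf("RPN loss %.6f = cls %.6f (N=%d) + %.2f * reg %.6f (N=%d)\n",
              x$total, x$cls_term, x$n_cls, x$lambda, x$reg_term, x$n_reg))
  invisible(x)
}

#' Select proposals by score with greedy non-maximum suppression
#'
#' Boxes are ranked by descending score (ties broken by lower row index),
#' truncated to `pre_nms_top_k`, greedily suppressed at IoU `nms_iou`, and
#' truncated again to `post_nms_top_k`. Deterministic for fixed inputs.
#'
#' @param boxes n x 4 box matrix.
#' @param scores length-n scores in `[0, 1]`.
#' @param pre_nms_top_k,post_nms_top_k truncation sizes.
#' @param nms_iou suppression IoU threshold.
#' @return List with `boxes`, `scores` and `keep` (kept row indices of the
#'   input).
#' @export
select_proposals <- function(boxes, scores, pre_nms_top_k = 1000,
                             nms_iou = 0.7, post_nms_top_k = 300) {
  boxes <- as_box_matrix(boxes)
  stopifnot(length(scores) == nrow(boxes))
  ord <- order(-scores, seq_along(scores))
  ord <- ord[seq_len(min(pre_nms_top_k, length(ord)))]
  keep <- integer(0)
  while (length(ord) > 0L) {
    i <- ord[1]
    keep <- c(keep, i)
    if (length(keep) >= post_nms_top_k) break
    ord <- ord[-1]
    if (length(ord) == 0L) break
    ious <- box_iou(boxes[i, , drop = FALSE], boxes[ord, , drop = FALSE])[1, ]
    ord <- ord[ious < nms_iou]
  }
  list(boxes = boxes[keep, , drop = FALSE], scores = scores[keep], keep = keep)
}

#' Write proposals as a plain-text box list
#'
#' One proposal per line: `x1 y1 x2 y2 score`, 0-based half-open coordinates.
#'
#' @param proposals list with `boxes` and `scores` (as from
#'   [select_proposals()]).
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_proposals <- function(proposals, path) {
  m <- cbind(proposals$boxes, proposals$scores)
  writeLines(apply(m, 1, function(r) paste(format(r, trim = TRUE), collapse = " ")),
             path)
  invisible(path)
}
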