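test_that("anchor counts multiply scales, ratios and locations", {
  a9 <- generate_anchors(c(8, 16, 32), c(0.5, 1, 2), c(1L, 1L), 8)
  expect_equal(nrow(a9), 9)
  a36 <- generate_anchors(c(8, 16, 32), c(0.5, 1, 2), c(2L, 2L), 8)
  expect_equal(nrow(a36), 36)
  expect_error(generate_anchors(scales = c(-1, 2, 3)), "positive")
})

test_that("anchor area is invariant under ratio at fixed scale; ratio 1 is square", {
  a <- generate_anchors(16, c(0.5, 1, 2), c(1L, 1L), 4)
  areas <- (a[, 3] - a[, 1]) * (a[, 4] - a[, 2])
  expect_equal(areas, rep(256, 3))
  sq <- generate_anchors(16, 1, c(1L, 1L), 4)
  expect_equal(sq[, 3] - sq[, 1], 16)
  expect_equal(sq[, 4] - sq[, 2], 16)
  expect_equal((sq[, 1] + sq[, 3]) / 2, 0.5 * 4)  # centered on the location
})

test_that("box encoding matches the hand example and inverts exactly", {
  anchor <- c(8, 8, 12, 12)               # center (10,10), size (4,4)
  box <- c(8, 8, 16, 12)                  # center (12,10), size (8,4)
  expect_equal(unname(encode_boxes(box, anchor)[1, ]), c(0.5, 0, log(2), 0))
  expect_equal(unname(encode_boxes(anchor, anchor)[1, ]), c(0, 0, 0, 0))
  dec <- decode_boxes(matrix(c(0.5, 0, log(2), 0), 1), anchor)
  expect_equal(dec[1, ], box)
  expect_equal(decode_boxes(matrix(0, 1, 4), anchor)[1, ], anchor)
})

test_that("encode/decode round-trips 1000 random box/anchor pairs", {
  set.seed(7)
  n <- 1000
  # box/anchor size ratios stay inside the documented decode clamp
  rand_boxes <- function() {
    x1 <- runif(n, 0, 100); y1 <- runif(n, 0, 100)
    cbind(x1, y1, x1 + runif(n, 2, 60), y1 + runif(n, 2, 60))
  }
  b <- rand_boxes(); a <- rand_boxes()
  err <- max(abs(decode_boxes(encode_boxes(b, a), a) - b))
  expect_lt(err, 1e-5)
  expect_error(encode_boxes(b, cbind(a[, 1], a[, 2], a[, 1], a[, 4])),
               "degenerate")
})

test_that("smooth_l1 is the stated piecewise form, continuous and nonnegative", {
  expect_equal(smooth_l1(0), 0)
  expect_equal(smooth_l1(1), 0.5)
  expect_equal(smooth_l1(-3), 2.5)
  eps <- 1e-8
  expect_lt(abs(smooth_l1(1 + eps) - smooth_l1(1 - eps)), 1e-7)
  x <- seq(-0.999, 0.999, length.out = 101)
  expect_equal(smooth_l1(x), x^2 / 2)
  expect_true(all(smooth_l1(seq(-5, 5, 0.1)) >= 0))
})

test_that("anchor assignment uses thresholds, rescue and the no-gt rule", {
  gt <- matrix(c(0, 0, 10, 10), 1)
  anchors <- rbind(c(0, 0, 10, 10),   # IoU 1 -> positive
                   c(0, 0, 10, 5),    # IoU 0.5, not best -> ignore
                   c(50, 50, 60, 60)) # IoU 0 -> negative
  asg <- assign_anchors(anchors, gt)
  expect_equal(asg$label, c("positive", "ignore", "negative"))
  expect_equal(asg$gt_index, c(1L, NA, NA))
  none <- assign_anchors(anchors, matrix(0, 0, 4))
  expect_true(all(none$label == "negative"))
  # rescue: an anchor below iou_hi still turns positive when it is the best
  far <- rbind(c(0, 0, 10, 5), c(30, 30, 40, 40))
  asg2 <- assign_anchors(far, gt)
  expect_equal(asg2$label[1], "positive")
})

test_that("every overlapped ground truth gets at least one positive anchor", {
  set.seed(21)
  for (rep in 1:20) {
    anchors <- generate_anchors(c(8, 16), c(0.5, 1, 2), c(6L, 6L), 8)
    k <- sample(1:4, 1)
    x1 <- runif(k, 0, 38); y1 <- runif(k, 0, 38)
    gt <- cbind(x1, y1, x1 + runif(k, 4, 10), y1 + runif(k, 4, 10))
    asg <- assign_anchors(anchors, gt)
    iou <- box_iou(anchors, gt)
    for (j in seq_len(k)) {
      if (any(iou[, j] > 0))
        expect_true(any(asg$label == "positive" & iou[, j] > 0))
    }
  }
})

test_that("the RPN objective behaves per its definition", {
  gt <- matrix(c(0, 0, 10, 10), 1)
  anchors <- rbind(c(0, 0, 10, 10), c(0, 0, 10, 5), c(50, 50, 60, 60))
  asg <- assign_anchors(anchors, gt)
  t_star <- encode_boxes(rbind(gt[1, ], gt[1, ], gt[1, ]), anchors)
  # perfect predictions: p = p*, t = t*
  perfect <- rpn_loss(c(1, 0.5, 0), asg, t_star, t_star)
  expect_lt(perfect$total, 1e-5)
  # single positive with t - t* = (1, 0, 0, 0)
  t_pred <- t_star; t_pred[1, 1] <- t_star[1, 1] + 1
  one <- rpn_loss(c(1, 0.5, 0), asg, t_pred, t_star, lambda = 1, n_reg = 1)
  expect_equal(one$reg_term, 0.5)
  # doubling lambda doubles only the regression term
  l2 <- rpn_loss(c(0.8, 0.5, 0.1), asg, t_pred, t_star, lambda = 2)
  l1 <- rpn_loss(c(0.8, 0.5, 0.1), asg, t_pred, t_star, lambda = 1)
  expect_equal(l2$cls_term, l1$cls_term)
  expect_equal(l2$total - l2$cls_term, 2 * (l1$total - l1$cls_term))
  # ignore-labeled anchors never change the loss
  p1 <- c(0.8, 0.1, 0.1); p2 <- c(0.8, 0.9, 0.1)
  tp2 <- t_pred; tp2[2, ] <- rnorm(4)
  expect_equal(rpn_loss(p1, asg, t_pred, t_star)$total,
               rpn_loss(p2, asg, tp2, t_star)$total)
  # empty positive set: regression term 0
  neg_only <- assign_anchors(matrix(c(50, 50, 60, 60), 1), gt)
  expect_equal(rpn_loss(0.2, neg_only, matrix(0, 1, 4),
                        matrix(0, 1, 4))$reg_term, 0)
})

test_that("greedy NMS matches a quadratic reference and its invariants", {
  nms_reference <- function(boxes, scores, thr) {
    ord <- order(-scores, seq_along(scores))
    keep <- integer(0)
    alive <- rep(TRUE, length(scores))
    for (i in ord) {
      if (!alive[i]) next
      keep <- c(keep, i)
      for (j in ord) {
        if (alive[j] && j != i &&
            box_iou(boxes[i, , drop = FALSE], boxes[j, , drop = FALSE])[1, 1] >= thr)
          alive[j] <- FALSE
      }
      alive[i] <- FALSE
    }
    keep
  }
  two <- rbind(c(0, 0, 10, 10), c(0, 0, 10, 10))
  out <- select_proposals(two, c(0.9, 0.8), nms_iou = 0.5)
  expect_equal(out$keep, 1L)
  disj <- rbind(c(0, 0, 5, 5), c(10, 10, 15, 15), c(20, 20, 25, 25))
  expect_equal(select_proposals(disj, c(0.3, 0.9, 0.5), nms_iou = 0.5)$keep,
               c(2L, 3L, 1L))
  set.seed(33)
  for (rep in 1:100) {
    n <- 50
    x1 <- runif(n, 0, 80); y1 <- runif(n, 0, 80)
    boxes <- cbind(x1, y1, x1 + runif(n, 2, 20), y1 + runif(n, 2, 20))
    scores <- round(runif(n), 2)  # rounded scores force ties
    got <- select_proposals(boxes, scores, nms_iou = 0.4)
    expect_equal(got$keep, nms_reference(boxes, scores, 0.4))
    expect_true(all(got$keep %in% seq_len(n)))
    if (length(got$keep) > 1) {
      iou <- box_iou(got$boxes, got$boxes)
      expect_true(all(iou[upper.tri(iou)] < 0.4))
    }
  }
})

test_that("proposals export as a plain-text box list", {
  sel <- list(boxes = rbind(c(0, 1, 5, 6), c(2, 3, 9, 9)), scores = c(0.9, 0.4))
  f <- withr::local_tempfile(fileext = ".txt")
  write_proposals(sel, f)
  lines <- readLines(f)
  expect_length(lines, 2)
  expect_equal(scan(text = lines[1], quiet = TRUE), c(0, 1, 5, 6, 0.9))
})
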