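# Object- and pixel-level scoring of instance segmentations.
#
# A label map is an integer matrix: 0 = background, positive ids = instances.
# Pixel geometry uses 0-based half-open boxes [x1, x2) x [y1, y2) with x along
# columns and y along rows.

#' Tight bounding box of a binary mask
#'
#' Computes the axis-aligned bounding box of the foreground pixels of a mask,
#' the way ground-truth detection boxes are derived from instance annotations:
#' the left-most/top-most and right-most/bottom-most foreground pixels define
#' the corner vertices, returned in the 0-based half-open convention.
#'
#' @param mask logical or 0/1 integer matrix (rows = y, columns = x).
#' @return Numeric vector `c(x1, y1, x2, y2)` with `x2 > x1`, `y2 > y1`.
#' @examples
#' m <- matrix(0L, 6, 8); m[3:5, 2:7] <- 1L
#' mask_to_bbox(m)  # c(1, 2, 7, 5)
#' @export
mask_to_bbox <- function(mask) {
  if (!is.matrix(mask)) stopf("`mask` must be a matrix")
  idx <- which(mask != 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) stopf("mask has no foreground pixels")
  c(min(idx[, 2]) - 1, min(idx[, 1]) - 1, max(idx[, 2]), max(idx[, 1]))
}

#' Jaccard index of two pixel sets or boxes
#'
#' Ratio of intersection area to union area. Accepts either two boxes
#' (`c(x1, y1, x2, y2)`, half-open) or two logical/binary matrices of equal
#' size interpreted as pixel sets.
#'
#' @param a,b boxes or binary matrices.
#' @return Jaccard similarity in `[0, 1]`.
#' @export
jaccard <- function(a, b) {
  if (is.matrix(a) && is.matrix(b)) {
    if (!all(dim(a) == dim(b))) stopf("pixel sets must share dimensions")
    av <- a != 0; bv <- b != 0
    u <- sum(av | bv)
    if (u == 0L) stopf("both pixel sets are empty")
    return(sum(av & bv) / u)
  }
  ia <- c(max(a[1], b[1]), max(a[2], b[2]), min(a[3], b[3]), min(a[4], b[4]))
  inter <- max(0, ia[3] - ia[1]) * max(0, ia[4] - ia[2])
  area <- function(bb) max(0, bb[3] - bb[1]) * max(0, bb[4] - bb[2])
  u <- area(a) + area(b) - inter
  if (u <= 0) stopf("both boxes are empty")
  inter / u
}

# contingency of instance overlaps: rows gt ids, cols pred ids (pixel counts)
instance_overlap_table <- function(gt, pred) {
  gids <- sort(unique(gt[gt > 0]))
  pids <- sort(unique(pred[pred > 0]))
  both <- gt > 0 & pred > 0
  tab <- matrix(0, length(gids), length(pids), dimnames = list(gids, pids))
  if (any(both) && length(gids) && length(pids)) {
    key <- paste(gt[both], pred[both])
    cnt <- table(key)
    parts <- strsplit(names(cnt), " ", fixed = TRUE)
    for (i in seq_along(cnt)) {
      tab[parts[[i]][1], parts[[i]][2]] <- as.numeric(cnt[[i]])
    }
  }
  list(tab = tab, gids = gids, pids = pids,
       garea = vapply(gids, function(i) sum(gt == i), numeric(1)),
       parea = vapply(pids, function(i) sum(pred == i), numeric(1)))
}

#' Match predicted to ground-truth instances and count detections
#'
#' Greedy one-to-one matching in descending instance IoU. Pairs whose IoU
#' reaches `iou_threshold` are true positives; unmatched predictions are false
#' positives and unmatched ground-truth instances false negatives.
#'
#' @param gt,pred integer label maps of equal size (0 = background).
#' @param iou_threshold minimum IoU for a valid match (default 0.5).
#' @return List with `counts` (TP, FP, FN) and `pairs`, a data frame of
#'   matched (gt, pred, iou) triples.
#' @export
match_instances <- function(gt, pred, iou_threshold = 0.5) {
  if (!all(dim(gt) == dim(pred))) stopf("label maps must share dimensions")
  ov <- instance_overlap_table(gt, pred)
  ng <- length(ov$gids); np <- length(ov$pids)
  pairs <- data.frame(gt = integer(), pred = integer(), iou = numeric())
  if (ng > 0L && np > 0L) {
    iou <- ov$tab / (outer(ov$garea, ov$parea, "+") - ov$tab)
    cand <- which(iou >= iou_threshold, arr.ind = TRUE)
    if (nrow(cand) > 0L) {
      vals <- iou[cand]
      ord <- order(-vals, cand[, 1], cand[, 2])
      used_g <- logical(ng); used_p <- logical(np)
      for (k in ord) {
        gi <- cand[k, 1]; pi <- cand[k, 2]
        if (used_g[gi] || used_p[pi]) next
        used_g[gi] <- TRUE; used_p[pi] <- TRUE
        pairs <- rbind(pairs, data.frame(gt = ov$gids[gi], pred = ov$pids[pi],
                                         iou = iou[gi, pi]))
      }
    }
  }
  tp <- nrow(pairs)
  list(counts = c(TP = tp, FP = np - tp, FN = ng - tp), pairs = pairs)
}

#' F1 score from detection counts
#'
#' `F1 = 2 TP / (2 TP + FP + FN)`, the harmonic mean of precision and recall
#' at the object level.
#'
#' @param counts named numeric vector with elements TP, FP, FN (as produced by
#'   [match_instances()]), or a list containing such a `counts` element.
#' @return F1 score in `[0, 1]`.
#' @examples
#' f1_score(c(TP = 8, FP = 2, FN = 2))  # 0.8
#' @export
f1_score <- function(counts) {
  if (is.list(counts) && !is.null(counts$counts)) counts <- counts$counts
  tp <- counts[["TP"]]; fp <- counts[["FP"]]; fn <- counts[["FN"]]
  if (any(c(tp, fp, fn) < 0)) stopf("counts must be non-negative")
  if (tp + fp + fn == 0) stopf("no instances to score")
  2 * tp / (2 * tp + fp + fn)
}

#' Aggregated Jaccard index
#'
#' Instance-aware pixel-level agreement between a ground-truth and a predicted
#' label map. For every ground-truth instance the prediction with the highest
#' Jaccard index is selected (ties broken by the lowest prediction id); its
#' intersection and union pixel counts are accumulated and the prediction is
#' marked used. A ground-truth instance overlapped by no prediction adds its
#' own pixel count to the union. After the loop every unused prediction adds
#' its full pixel count to the union, penalizing spurious instances. The score
#' is the ratio of accumulated intersections to accumulated unions.
#'
#' @param gt,pred integer label maps of equal size.
#' @return AJI score in `[0, 1]`.
#' @export
aji <- function(gt, pred) {
  if (!all(dim(gt) == dim(pred))) stopf("label maps must share dimensions")
  ov <- instance_overlap_table(gt, pred)
  ng <- length(ov$gids); np <- length(ov$pids)
  if (ng == 0L) stopf("ground truth contains no instances")
  if (np == 0L) return(0)
  iou <- ov$tab / (outer(ov$garea, ov$parea, "+") - ov$tab)
  C <- 0; U <- 0
  used <- logical(np)
  for (gi in seq_len(ng)) {
    best <- which.max(iou[gi, ])  # first maximum = lowest prediction id
    if (iou[gi, best] > 0) {
      C <- C + ov$tab[gi, best]
      U <- U + ov$garea[gi] + ov$parea[best] - ov$tab[gi, best]
      used[best] <- TRUE
    } else {
      U <- U + ov$garea[gi]
    }
  }
  U <- U + sum(ov$parea[!used])
  C / U
}

#' Brute-force AJI reference
#'
#' Independent re-implementation of [aji()] by naive pixel-set enumeration
#' (explicit `intersect`/`union` on pixel index vectors, no shared code),
#' intended as a cross-check on small maps.
#'
#' @inheritParams aji
#' @return AJI score in `[0, 1]`.
#' @export
aji_bruteforce_oracle <- function(gt, pred) {
  if (!all(dim(gt) == dim(pred))) stopf("label maps must share dimensions")
  gids <- sort(unique(as.vector(gt))); gids <- gids[gids > 0]
  pids <- sort(unique(as.vector(pred))); pids <- pids[pids > 0]
  if (length(gids) == 0L) stopf("ground truth contains no instances")
  if (length(pids) == 0L) return(0)
  gsets <- lapply(gids, function(i) which(gt == i))
  psets <- lapply(pids, function(i) which(pred == i))
  C <- 0; U <- 0
  used <- rep(FALSE, length(pids))
  for (g in gsets) {
    best_j <- 0L; best_jac <- 0
    for (j in seq_along(psets)) {
      inter <- length(intersect(g, psets[[j]]))
      jac <- inter / length(union(g, psets[[j]]))
      if (jac > best_jac) { best_jac <- jac; best_j <- j }
    }
    if (best_j > 0L) {
      C <- C + length(intersect(g, psets[[best_j]]))
      U <- U + length(union(g, psets[[best_j]]))
      used[best_j] <- TRUE
    } else {
      U <- U + length(g)
    }
  }
  for (j in seq_along(psets)) if (!used[j]) U <- U + length(psets[[j]])
  C / U
}
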