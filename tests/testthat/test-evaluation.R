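test_that("mask_to_bbox scans min/max foreground pixels", {
  m <- matrix(0L, 8, 8); m[4, 6] <- 1L           # row 4, col 6 (1-based)
  expect_equal(mask_to_bbox(m), c(5, 3, 6, 4))   # 0-based half-open
  full <- matrix(1L, 5, 9)
  expect_equal(mask_to_bbox(full), c(0, 0, 9, 5))
  L <- matrix(0L, 8, 8)
  L[3:5, 2] <- 1L; L[5, 2:7] <- 1L               # rows 3-5, cols 2-7
  expect_equal(mask_to_bbox(L), c(1, 2, 7, 5))
  expect_error(mask_to_bbox(matrix(0L, 3, 3)), "foreground")
})

test_that("jaccard handles boxes and pixel sets", {
  a <- matrix(0L, 4, 4); a[1, 1:4] <- 1L
  b <- matrix(0L, 4, 4); b[1, 3:4] <- 1L; b[2, 1:2] <- 1L
  expect_equal(jaccard(a, a), 1)
  expect_equal(jaccard(a, b), 1 / 3)  # 4 px and 4 px sharing 2 px
  expect_equal(jaccard(a, matrix(c(0L, 1L, 0L, 0L), 4, 4) * 0 +
                          {z <- matrix(0L, 4, 4); z[4, 4] <- 1L; z}), 0)
  expect_error(jaccard(matrix(0L, 2, 2), matrix(0L, 2, 2)), "empty")
  expect_equal(jaccard(c(0, 0, 2, 2), c(1, 1, 3, 3)), 1 / 7)
})

test_that("instance matching counts TP/FP/FN correctly", {
  gt <- rand_label_map(24, 24, 4, seed = 3)
  self <- match_instances(gt, gt)
  n <- length(unique(gt[gt > 0]))
  expect_equal(unname(self$counts), c(n, 0, 0))
  none <- match_instances(gt, matrix(0L, 24, 24))
  expect_equal(unname(none$counts), c(0, 0, n))
})

test_that("greedy matching agrees with exhaustive optimal assignment", {
  count_optimal <- function(gt, pred, thr = 0.5) {
    gids <- sort(unique(gt[gt > 0])); pids <- sort(unique(pred[pred > 0]))
    if (!length(gids) || !length(pids)) return(0L)
    iou <- matrix(0, length(gids), length(pids))
    for (i in seq_along(gids)) for (j in seq_along(pids))
      iou[i, j] <- sum(gt == gids[i] & pred == pids[j]) /
                   sum(gt == gids[i] | pred == pids[j])
    valid <- iou >= thr
    best <- 0L
    recurse <- function(i, used, acc) {
      if (i > length(gids)) { best <<- max(best, acc); return(invisible()) }
      recurse(i + 1L, used, acc)
      for (j in which(valid[i, ] & !used)) {
        used[j] <- TRUE
        recurse(i + 1L, used, acc + 1L)
        used[j] <- FALSE
      }
    }
    recurse(1L, logical(length(pids)), 0L)
    best
  }
  for (s in 1:50) {
    gt <- rand_label_map(20, 20, sample(2:6, 1), seed = s)
    pred <- rand_label_map(20, 20, sample(2:6, 1), seed = s + 1000)
    got <- match_instances(gt, pred, 0.5)$counts[["TP"]]
    expect_equal(got, count_optimal(gt, pred, 0.5))
  }
})

test_that("F1 follows 2TP/(2TP+FP+FN)", {
  expect_equal(f1_score(c(TP = 8, FP = 2, FN = 2)), 0.8)
  expect_equal(f1_score(c(TP = 5, FP = 0, FN = 0)), 1)
  expect_equal(f1_score(c(TP = 0, FP = 3, FN = 2)), 0)
  expect_error(f1_score(c(TP = 0, FP = 0, FN = 0)), "no instances")
})

test_that("AJI reproduces the hand-computed examples", {
  gt <- matrix(0L, 4, 4); gt[1, 1:4] <- 1L               # one 4-px instance
  pr <- matrix(0L, 4, 4); pr[1, 3:4] <- 1L; pr[2, 1:2] <- 1L
  expect_equal(aji(gt, pr), 1 / 3)                        # C=2, U=6
  gt2 <- matrix(0L, 4, 4); gt2[2, 2:3] <- 1L              # one 2-px instance
  pr2 <- gt2; pr2[4, 1:3] <- 2L                           # + disjoint 3 px
  expect_equal(aji(gt2, pr2), 0.4)                        # C=2, U=5
  expect_equal(aji(gt, gt), 1)
  expect_equal(aji(gt, matrix(0L, 4, 4)), 0)
  expect_error(aji(matrix(0L, 4, 4), pr), "no instances")
})

test_that("aji agrees exactly with the brute-force oracle on random maps", {
  for (s in 1:100) {
    gt <- rand_label_map(28, 28, sample(1:8, 1), seed = s)
    pred <- rand_label_map(28, 28, sample(0:8, 1), seed = s + 5000)
    expect_identical(aji(gt, pred), aji_bruteforce_oracle(gt, pred))
  }
})

test_that("AJI is 1 exactly for id permutations and penalized by spurious instances", {
  gt <- rand_label_map(24, 24, 5, seed = 42)
  perm <- gt
  ids <- sort(unique(gt[gt > 0]))
  for (k in seq_along(ids)) perm[gt == ids[k]] <- rev(ids)[k]
  expect_equal(aji(gt, perm), 1)
  base <- aji(gt, gt)
  spur <- gt
  stopifnot(all(spur[1:2, 23:24] == 0))
  spur[1:2, 23:24] <- max(ids) + 1L
  expect_lt(aji(gt, spur), base)
  vals <- replicate(20, {
    p <- rand_label_map(24, 24, 4, seed = sample.int(1e6, 1))
    aji(gt, p)
  })
  expect_true(all(vals >= 0 & vals <= 1))
})
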