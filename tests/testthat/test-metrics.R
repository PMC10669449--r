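test_that("box IOU handles identity, disjoint and partial overlap", {
  expect_equal(box_iou(c(0, 0, 2, 2), c(0, 0, 2, 2)), 1)
  expect_equal(box_iou(c(0, 0, 2, 2), c(5, 5, 7, 9)), 0)
  expect_equal(box_iou(c(0, 0, 2, 2), c(1, 1, 3, 3)), 1 / 7)
  expect_equal(box_iou(c(0, 0, 0, 0), c(0, 0, 5, 5)), 0)  # empty box
  expect_error(box_iou(c(2, 0, 1, 2), c(0, 0, 1, 1)), "malformed")
})

test_that("box IOU equals the pixel-set counting oracle on random boxes with sides up to 20", {
  set.seed(71)
  for (i in 1:400) {
    a0 <- sample(0:10, 2); b0 <- sample(0:10, 2)
    a <- c(a0, a0 + sample(0:20, 2))
    b <- c(b0, b0 + sample(0:20, 2))
    expect_equal(box_iou(a, b), pixel_box_iou(a, b))
  }
})

test_that("box IOU and mask metrics are symmetric", {
  set.seed(8)
  a <- c(1, 2, 7, 9); b <- c(3, 0, 12, 5)
  expect_equal(box_iou(a, b), box_iou(b, a))
  m1 <- random_mask(12); m2 <- random_mask(12)
  expect_equal(dice(m1, m2), dice(m2, m1))
  expect_equal(jaccard(m1, m2), jaccard(m2, m1))
})

test_that("dice and jaccard match pixel-count oracles and their algebraic identity", {
  a <- matrix(FALSE, 4, 4); b <- a
  a[1, 1:4] <- TRUE           # |A| = 4
  b[1, 3:4] <- TRUE; b[2, 1:2] <- TRUE   # |B| = 4, overlap 2
  expect_equal(dice(a, b), 0.5)
  expect_equal(jaccard(a, b), 1 / 3)
  set.seed(9)
  for (i in 1:100) {
    m1 <- random_mask(9, runif(1, 0.05, 0.6))
    m2 <- random_mask(9, runif(1, 0.05, 0.6))
    inter <- sum(m1 & m2); un <- sum(m1 | m2)
    d_or <- if (sum(m1) + sum(m2) == 0) 1 else 2 * inter / (sum(m1) + sum(m2))
    j_or <- if (un == 0) 1 else inter / un
    d <- dice(m1, m2); j <- jaccard(m1, m2)
    expect_equal(d, d_or)
    expect_equal(j, j_or)
    expect_equal(j, d / (2 - d), tolerance = 1e-12)
    expect_true(j <= d + 1e-15 && d <= 1 && j >= 0)
  }
})

test_that("empty-mask conventions: both empty is perfect, one empty is zero", {
  e <- matrix(FALSE, 5, 5)
  f <- e; f[3, 3] <- TRUE
  expect_equal(dice(e, e), 1)
  expect_equal(jaccard(e, e), 1)
  expect_equal(dice(e, f), 0)
  expect_equal(jaccard(f, e), 0)
  expect_error(dice(e, matrix(FALSE, 4, 5)), "shape")
})

test_that("mask_bbox emits half-open 0-based boxes", {
  m <- matrix(FALSE, 8, 8)
  m[3:5, 2:4] <- TRUE
  expect_equal(mask_bbox(m), c(2, 1, 5, 4))
  expect_equal(mask_bbox(matrix(FALSE, 3, 3)), c(0, 0, 0, 0))
})

test_that("summary bins at {0.2, 0.5} are lower-inclusive and sum to one", {
  recs <- do.call(rbind, list(
    data.frame(id = "a", iou = 0.6, dice = 0.5, jaccard = 1 / 3, detected = TRUE),
    data.frame(id = "b", iou = 0.3, dice = 0.4, jaccard = 0.25, detected = TRUE),
    data.frame(id = "c", iou = 0.1, dice = 0.1, jaccard = 0.052, detected = FALSE)))
  s <- summarize_eval(recs)
  expect_equal(unname(unlist(s[1, 1:3])), rep(100 / 3, 3))
  expect_equal(s$mean_iou, 100 * mean(c(0.6, 0.3, 0.1)))
  expect_equal(s$pct_iou_50_100 + s$pct_iou_20_50 + s$pct_iou_0_20, 100)
  # boundary: exactly 0.5 counts in the top bin; exactly 0.2 in the middle
  sb <- summarize_eval(data.frame(id = c("d", "e"), iou = c(0.5, 0.2),
                                  dice = 0, jaccard = 0, detected = FALSE))
  expect_equal(sb$pct_iou_50_100, 50)
  expect_equal(sb$pct_iou_20_50, 50)
  expect_equal(sb$pct_iou_0_20, 0)
  perfect <- summarize_eval(data.frame(id = "f", iou = 1, dice = 1,
                                       jaccard = 1, detected = TRUE))
  expect_equal(perfect$pct_iou_50_100, 100)
  expect_equal(perfect$mean_iou, 100)
  expect_error(summarize_eval(recs[0, ]), "no evaluation records")
})

test_that("eval_record combines rectangle IOU with pixel-mask dice/jaccard", {
  pred <- matrix(FALSE, 10, 10); lab <- pred
  pred[2:5, 2:5] <- TRUE
  lab[4:7, 4:7] <- TRUE
  r <- eval_record(pred, lab, id = "x")
  expect_equal(r$iou, box_iou(mask_bbox(pred), mask_bbox(lab)))
  expect_equal(r$dice, dice(pred, lab))
  expect_true(r$detected)
})
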