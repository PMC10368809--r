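test_that("iou matches hand-counted examples and rejects the undefined case", {
  a <- matrix(FALSE, 6, 6); b <- a
  a[1:2, 1:2] <- TRUE           # 2 x 2 square
  b[2:3, 1:2] <- TRUE           # shifted down by one: overlap 2 px, union 6
  expect_equal(iou(a, b), 2 / 6)
  expect_equal(iou(a, a), 1)
  d <- matrix(FALSE, 6, 6); d[5:6, 5:6] <- TRUE
  expect_equal(iou(a, d), 0)
  expect_error(iou(matrix(FALSE, 2, 2), matrix(FALSE, 2, 2)), "undefined")
  expect_error(iou(a, matrix(FALSE, 2, 2)), "same shape")
})

test_that("matching handles identity, empty predictions and planted misses", {
  gt <- matrix(0L, 60, 60)
  gt <- drawDisk(gt, 12, 12, 6, 1L)
  gt <- drawDisk(gt, 40, 12, 6, 2L)
  gt <- drawDisk(gt, 25, 45, 6, 3L)
  m <- matchObjects(gt, gt)
  expect_equal(m@tp, 3L); expect_equal(m@fp, 0L); expect_equal(m@fn, 0L)

  m2 <- matchObjects(matrix(0L, 60, 60), gt)
  expect_equal(c(m2@tp, m2@fp, m2@fn), c(0L, 0L, 3L))

  ## shift one disk so its IoU drops below the threshold
  pred <- matrix(0L, 60, 60)
  pred <- drawDisk(pred, 12, 12, 6, 1L)
  pred <- drawDisk(pred, 40, 12, 6, 2L)
  pred <- drawDisk(pred, 25 + 7, 45, 6, 3L)
  ov <- iou(pred == 3L, gt == 3L)
  expect_lt(ov, 0.6)
  m3 <- matchObjects(pred, gt)
  expect_equal(c(m3@tp, m3@fp, m3@fn), c(2L, 1L, 1L))
})

test_that("the matched count is invariant to label permutation and the
           threshold is strict and monotone", {
  gt <- matrix(0L, 50, 50)
  gt <- drawDisk(gt, 12, 12, 6, 1L); gt <- drawDisk(gt, 35, 35, 6, 2L)
  perm <- gt; perm[gt == 1L] <- 2L; perm[gt == 2L] <- 1L
  m <- matchObjects(perm, gt)
  expect_equal(m@tp, 2L)
  met <- computeMetrics(m, perm, gt)
  expect_equal(met@f1, 1); expect_equal(met@pixelAccuracy, 1)

  ## a pair with IoU exactly at the threshold must stay unmatched (strict >)
  a <- matrix(0L, 10, 10); b <- matrix(0L, 10, 10)
  a[1:6, 1:5] <- 1L                      # 30 px
  b[1:6, 1:5] <- 1L; b[7:9, 1:5] <- 1L   # 45 px, IoU = 30/45 = 2/3
  expect_equal(iou(a > 0, b > 0), 2 / 3)
  expect_equal(matchObjects(a, b, iouThreshold = 2 / 3)@tp, 0L)
  expect_equal(matchObjects(a, b, iouThreshold = 0.6)@tp, 1L)

  ## raising the threshold never increases TP
  set.seed(4)
  gt2 <- matrix(0L, 80, 80); pred2 <- matrix(0L, 80, 80)
  for (k in 1:5) {
    cx <- 10 + 14 * (k - 1) %% 4 + 6; cy <- 15 + 30 * ((k - 1) %/% 4)
    gt2 <- drawDisk(gt2, cx, cy, 5, k)
    pred2 <- drawDisk(pred2, cx + sample(0:4, 1), cy, 5, k)
  }
  tps <- vapply(c(0.3, 0.5, 0.7, 0.9),
                function(th) matchObjects(pred2, gt2, th)@tp, integer(1))
  expect_true(all(diff(tps) <= 0))
})

test_that("greedy matching attains the brute-force optimal matched count", {
  set.seed(7)
  for (rep in 1:6) {
    nObj <- sample(3:8, 1)
    gt <- matrix(0L, 90, 90); pred <- matrix(0L, 90, 90)
    for (k in seq_len(nObj)) {
      cx <- sample(10:80, 1); cy <- sample(10:80, 1)
      gt <- drawDisk(gt, cx, cy, 5, k)
      pred <- drawDisk(pred, cx + sample(-3:3, 1), cy + sample(-3:3, 1), 5, k)
    }
    gt <- relabelMask(gt); pred <- relabelMask(pred)
    expect_equal(matchObjects(pred, gt)@tp, bruteForceMatchCount(pred, gt))
  }
})

test_that("metrics reproduce the precision/recall/F1 arithmetic", {
  m <- new("SegMatch",
           pairs = data.frame(pred = 1:8, gt = 1:8, iou = rep(0.9, 8)),
           tp = 8L, fp = 2L, fn = 2L, iouThreshold = 0.6)
  dummy <- matrix(0L, 4, 4)
  met <- computeMetrics(m, dummy, dummy)
  expect_equal(met@precision, 0.8)
  expect_equal(met@recall, 0.8)
  expect_equal(met@f1, 0.8)

  m0 <- new("SegMatch", pairs = data.frame(pred = integer(0),
                                           gt = integer(0),
                                           iou = numeric(0)),
            tp = 0L, fp = 3L, fn = 4L, iouThreshold = 0.6)
  met0 <- computeMetrics(m0, dummy, dummy)
  expect_equal(met0@f1, 0)
})

test_that("the nucleus detector resolves separated and touching disks", {
  expect_equal(max(suppressWarnings(detectNuclei(matrix(0, 40, 40)))), 0L)

  img <- matrix(0, 80, 80)
  img <- drawDisk(img, 20, 20, 10); img <- drawDisk(img, 60, 60, 10)
  set.seed(1)
  img <- img + matrix(rnorm(6400, 0, 0.1), 80, 80)   # SNR ~ 10
  expect_equal(max(detectNuclei(img)), 2L)

  img2 <- matrix(0, 80, 80)
  img2 <- drawDisk(img2, 30, 40, 10); img2 <- drawDisk(img2, 48, 40, 10)
  expect_equal(max(detectNuclei(img2)), 2L)
})

test_that("per-image and pooled summaries agree on identical mask lists", {
  gt <- matrix(0L, 50, 50)
  gt <- drawDisk(gt, 12, 12, 6, 1L); gt <- drawDisk(gt, 35, 35, 6, 2L)
  s <- segmentationSummary(list(gt, gt), list(gt, gt))
  expect_equal(unname(unlist(s["pooled", ])), c(1, 1, 1, 1))
  expect_equal(unname(unlist(s["per_image_mean", ])), c(1, 1, 1, 1))
})
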