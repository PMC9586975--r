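.oneGt <- function() groundTruthTable("im", 0, 0, 100, 100)

test_that("greedy evaluation matching labels TPs and FPs correctly", {
  gt <- .oneGt()
  hit <- detectionTable("im", 0, 0, 100, 100, 0.9)
  expect_true(matchForEval(gt, hit, 0.5)$tp)

  # IoU 0.6 fails a 0.75 threshold
  part <- detectionTable("im", 25, 0, 125, 100, 0.9)  # IoU = 75/125 = 0.6
  expect_equal(boxIoU(part, gt), 0.6)
  expect_false(matchForEval(gt, part, 0.75)$tp)
  expect_true(matchForEval(gt, part, 0.5)$tp)

  # two qualifying detections: the more confident wins the single GT
  two <- detectionTable("im", c(0, 1), c(0, 1), c(100, 101), c(100, 101),
                        score = c(0.6, 0.8))
  lab <- matchForEval(gt, two, 0.5)
  expect_equal(lab$tp, c(TRUE, FALSE))
  expect_equal(lab$score, c(0.8, 0.6))
  # oracle: exhaustive greedy assignment agrees
  expect_equal(lab$tp,
               labelOracle(as.matrix(gt[, 3:6]), as.matrix(two[, 3:6]),
                           two$score, 0.5))
})

test_that("101-point AP reproduces the canonical staircase values", {
  expect_equal(averagePrecision101(c(TRUE, FALSE), 1), 1)
  expect_equal(averagePrecision101(c(FALSE, TRUE), 1), 0.5)
  expect_equal(averagePrecision101(logical(0), 1), 0)
  expect_true(is.na(averagePrecision101(c(TRUE), 0)))
})

test_that("AP agrees with brute-force staircase enumeration", {
  set.seed(41)
  for (rep in 1:100) {
    n <- sample(0:6, 1)
    tp <- sample(c(TRUE, FALSE), n, replace = TRUE)
    nGt <- sample(1:4, 1)
    tp[cumsum(tp) > nGt] <- FALSE   # cannot have more TPs than GTs
    expect_equal(averagePrecision101(tp, nGt), apOracle(tp, nGt),
                 tolerance = 1e-9)
  }
})

test_that("average recall follows the IoU threshold grid", {
  gt <- .oneGt()
  expect_equal(averageRecall(gt, detectionTable("im", 0, 0, 100, 100, 0.9), 1), 1)
  # IoU 0.45: below every grid threshold
  low <- detectionTable("im", 100 * 0.55 / 1.45, 0, 100 + 100 * 0.55 / 1.45,
                        100, 0.9)
  expect_equal(boxIoU(low, gt), 0.45, tolerance = 1e-12)
  expect_equal(averageRecall(gt, low, 1), 0)
  # IoU exactly 0.72 passes thresholds .50-.70, fails .75-.95
  mid <- detectionTable("im", 1400 / 86, 0, 100 + 1400 / 86, 100, 0.9)
  expect_equal(boxIoU(mid, gt), 0.72)
  expect_equal(averageRecall(gt, mid, 1), 0.5)
})

test_that("AR truncates per image before matching, so AR_10 >= AR_1", {
  set.seed(42)
  gts <- groundTruthTable(rep(c("i1", "i2"), each = 2),
                          c(0, 300, 0, 300), c(0, 300, 0, 300),
                          c(100, 400, 100, 400), c(100, 400, 100, 400))
  b <- randomIntBoxes(12, 500, 500)
  dets <- detectionTable(rep(c("i1", "i2"), 6), b[, 1], b[, 2], b[, 3], b[, 4],
                         score = runif(12))
  dets <- rbind(dets, detectionTable("i1", 0, 0, 100, 100, 0.2))
  expect_gte(averageRecall(gts, dets, 10), averageRecall(gts, dets, 1))
})

test_that("the full report is perfect for a perfect detector and zero for none", {
  gts <- groundTruthTable(sprintf("im%d", 1:6), seq(0, 500, 100), 10,
                          seq(0, 500, 100) + c(50, 50, 50, 150, 150, 150), 10 +
                            c(50, 50, 50, 150, 150, 150))
  perfect <- detectionTable(gts$image_id, gts$x_min, gts$y_min, gts$x_max,
                            gts$y_max, score = seq(0.95, 0.7, length.out = 6))
  v <- metricValues(evaluateDetections(gts, perfect))
  expect_true(all(v[!is.na(v)] == 1))
  expect_false(is.na(v["ap_medium"]))  # 50x50 boxes are medium
  expect_false(is.na(v["ap_large"]))   # 150x150 boxes are large

  none <- perfect[0, ]
  v0 <- metricValues(evaluateDetections(gts, none))
  expect_true(all(v0[!is.na(v0)] == 0))
  expect_error(evaluateDetections(gts[0, ], perfect), "empty ground-truth")
})

test_that("AP is monotone in the IoU threshold and invariant to score rescaling", {
  set.seed(43)
  for (rep in 1:10) {
    nG <- sample(1:4, 1); nD <- sample(1:6, 1)
    g <- randomIntBoxes(nG, 200, 200); d <- randomIntBoxes(nD, 200, 200)
    gts <- groundTruthTable("im", g[, 1], g[, 2], g[, 3], g[, 4])
    scores <- runif(nD)
    dets <- detectionTable("im", d[, 1], d[, 2], d[, 3], d[, 4], scores)
    aps <- vapply(seq(0.5, 0.95, 0.05), function(t) {
      lab <- matchForEval(gts, dets, t)
      averagePrecision101(lab$tp, nG)
    }, 0)
    expect_true(all(diff(aps) <= 1e-12))
    # strictly monotone rescaling of all scores changes nothing
    dets2 <- dets; dets2$score <- dets$score^3
    expect_equal(metricValues(evaluateDetections(gts, dets2)),
                 metricValues(evaluateDetections(gts, dets)))
  }
})

test_that("size buckets restrict ground truths without off-bucket false positives", {
  gts <- groundTruthTable(c("a", "a"), c(0, 300), c(0, 300), c(50, 450),
                          c(50, 450))             # one medium, one large
  dets <- detectionTable(c("a", "a"), c(0, 300), c(0, 300), c(50, 450),
                         c(50, 450), score = c(0.9, 0.8))
  v <- metricValues(evaluateDetections(gts, dets))
  # the large detection matched to the large GT must not count as a medium FP
  expect_equal(unname(v["ap_medium"]), 1)
  expect_equal(unname(v["ap_large"]), 1)
  expect_equal(unname(v["ar_medium"]), 1)
})

test_that("fold summaries report mean and sample SD per metric", {
  mk <- function(val) new("MetricsReport",
                          values = setNames(rep(val, 10),
                                            stackbox:::.METRIC_NAMES),
                          nGroundTruth = 10L, nDetections = 10L)
  s <- crossvalSummary(list(mk(0.6), mk(0.6), mk(0.6), mk(0.6), mk(0.6)))
  expect_equal(s$mean, rep(0.6, 10))
  expect_equal(s$sd, rep(0, 10))
  s2 <- crossvalSummary(list(mk(0.5), mk(0.7)))
  expect_equal(s2$mean, rep(0.6, 10))
  expect_equal(s2$sd, rep(sd(c(0.5, 0.7)), 10))
  expect_equal(round(s2$sd[1], 2), 0.14)
  expect_error(crossvalSummary(list(mk(0.5))), "at least two")
  tab <- formatMetricsTable(list(modelA = s2))
  expect_match(tab[1], "ap_50")
  expect_match(tab[3], "0.60 ± 0.14")
})
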