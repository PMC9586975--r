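test_that("matching picks each model's best-IoU detection per ground truth", {
  fx <- fillRuleFixture()
  mt <- matchToGroundTruth(fx$gts, fx$dets, fx$roster)
  # gt1: a and c overlap, b has nothing; gt2: all three; gt3: nobody
  expect_equal(is.na(mt$detIdx[1, ]), c(a = FALSE, b = TRUE, c = FALSE))
  expect_equal(is.na(mt$detIdx[2, ]), c(a = FALSE, b = FALSE, c = FALSE))
  expect_true(all(is.na(mt$detIdx[3, ])))
  expect_true(all(mt$iou[2, ] > 0 & mt$iou[2, ] <= 1))
})

test_that("non-exclusive matching lets one detection serve several ground truths", {
  gts <- groundTruthTable("im", c(0, 30), c(0, 0), c(40, 70), c(40, 40))
  dets <- rbind(
    detectionTable("im", 10, 0, 50, 40, 0.9, "a"),
    detectionTable("im", 0, 0, 40, 40, 0.9, "b"))
  mt <- matchToGroundTruth(gts, dets, c("a", "b"))
  # brute-force argmax over all (gt, det) pairs for model a
  expect_equal(mt$detIdx[1, "a"], mt$detIdx[2, "a"])  # same detection, both gts
  ious <- iouMatrix(gts, dets[1, ])
  expect_equal(mt$iou[, "a"], as.numeric(ious))
  # exclusive greedy assignment claims it for the first gt only
  mtEx <- matchToGroundTruth(gts, dets, c("a", "b"), exclusive = TRUE)
  expect_false(is.na(mtEx$detIdx[1, "a"]))
  expect_true(is.na(mtEx$detIdx[2, "a"]))
})

test_that("imputation fills empty slots from the row's best match and flags them", {
  fx <- fillRuleFixture()
  mt <- imputeAndFilter(matchToGroundTruth(fx$gts, fx$dets, fx$roster))
  # gt3 (matched by nobody) dropped
  expect_equal(nrow(mt$gt), 2L)
  expect_equal(mt$keptRows, 1:2)
  # gt1: slot b imputed from a (higher IoU than c)
  expect_equal(unname(mt$fillFlags[1, ]), c(FALSE, TRUE, FALSE))
  expect_equal(unname(mt$detIdx[1, "b"]), unname(mt$detIdx[1, "a"]))
  # fully matched row untouched
  expect_equal(unname(mt$fillFlags[2, ]), c(FALSE, FALSE, FALSE))
  expect_true(all(!is.na(mt$detIdx[1:2, ])))
})

test_that("imputed coordinates always copy a matched detection of the same row", {
  set.seed(31)
  sc <- presetScenario("bias", nImages = 40, seed = 5)
  sim <- simulateScenario(sc)
  mt <- imputeAndFilter(matchToGroundTruth(sim$gts, sim$dets, sim$roster))
  ds <- buildCoordinateDatasets(mt)
  for (r in which(rowSums(mt$fillFlags) > 0)) {
    filled <- which(mt$fillFlags[r, ])
    real <- which(!mt$fillFlags[r, ])
    for (j in filled)
      expect_true(mt$detIdx[r, j] %in% mt$detIdx[r, real])
  }
})

test_that("coordinate datasets share shape, alignment and roster column order", {
  fx <- fillRuleFixture()
  mt <- imputeAndFilter(matchToGroundTruth(fx$gts, fx$dets, fx$roster))
  ds <- buildCoordinateDatasets(mt)
  expect_named(ds, c("x_min", "y_min", "x_max", "y_max"))
  for (d in ds) {
    expect_equal(dim(d$X), c(2L, 3L))
    expect_equal(colnames(d$X), fx$roster)
    expect_length(d$y, 2L)
  }
  expect_equal(ds$x_min$y, fx$gts$x_min[1:2])
  # slots all holding one box yield a constant predictor row
  gts1 <- groundTruthTable("im", 4, 6, 19, 21)
  dets1 <- do.call(rbind, lapply(c("a", "b", "c"), function(m)
    detectionTable("im", 5, 5, 20, 20, 0.9, m)))
  ds1 <- buildCoordinateDatasets(imputeAndFilter(
    matchToGroundTruth(gts1, dets1, c("a", "b", "c"))))
  expect_equal(unname(ds1$x_min$X[1, ]), c(5, 5, 5))
  expect_equal(ds1$x_min$y, 4)
  # permuting the roster permutes predictor columns identically everywhere
  mtP <- imputeAndFilter(matchToGroundTruth(fx$gts, fx$dets, rev(fx$roster)))
  dsP <- buildCoordinateDatasets(mtP)
  for (coord in names(ds))
    expect_equal(dsP[[coord]]$X, ds[[coord]]$X[, rev(fx$roster)])
})

test_that("identity base learners give an identity least-squares fit", {
  set.seed(32)
  sc <- presetScenario("perfect", nImages = 25, seed = 9)
  sim <- simulateScenario(sc)
  fit <- stackBoxFit(sim$gts, sim$dets, sim$roster)
  ds <- buildCoordinateDatasets(imputeAndFilter(
    matchToGroundTruth(sim$gts, sim$dets, sim$roster)))
  for (coord in names(ds)) {
    pred <- cbind(1, ds[[coord]]$X) %*%
      replace(fit@models[[coord]]$coef, is.na(fit@models[[coord]]$coef), 0)
    expect_lt(sqrt(mean((pred - ds[[coord]]$y)^2)), 1e-6)
  }
})

test_that("a pure coordinate shift is corrected by the least-squares fit", {
  set.seed(33)
  n <- 60
  x0 <- runif(n, 0, 500); y0 <- runif(n, 0, 500)
  gts <- groundTruthTable(sprintf("im%03d", 1:n), x0, y0, x0 + 80, y0 + 80)
  mk <- function(m, dx) detectionTable(gts$image_id, gts$x_min + dx, gts$y_min,
                                       gts$x_max + dx, gts$y_max, 0.9, m)
  dets <- rbind(mk("a", 5), mk("b", 0))   # model a shifted +5 px in x only
  fit <- stackBoxFit(gts, dets, c("a", "b"))
  rows <- deduplicateRows(assembleTestRows(dets, c("a", "b")))
  pred <- predictBoxes(fit, rows)
  lab <- matchForEval(gts, finalizeDetections(pred), iouThreshold = 0.99)
  expect_true(all(lab$tp))   # shift corrected to near-exact boxes
})

test_that("fit validates its configuration", {
  fx <- fillRuleFixture()
  expect_error(stackBoxFit(fx$gts, fx$dets[fx$dets$model_id == "a", ], "a"),
               "at least two")
  expect_error(stackBoxFit(fx$gts, fx$dets, fx$roster, regressor = "mystery"),
               "unknown regressor")
  bad <- fx$dets; bad$model_id[1] <- "stranger"
  expect_error(matchToGroundTruth(fx$gts, bad, fx$roster), "roster")
})

test_that("tree-ensemble backends fit, predict, and are seed-deterministic", {
  sc <- presetScenario("bias", nImages = 30, seed = 4)
  sim <- simulateScenario(sc)
  for (kind in c("rf", "xgb")) {
    f1 <- stackBoxFit(sim$gts, sim$dets, sim$roster, regressor = kind, seed = 7)
    f2 <- stackBoxFit(sim$gts, sim$dets, sim$roster, regressor = kind, seed = 7)
    p1 <- suppressMessages(stackBoxPredict(f1, sim$dets))
    p2 <- suppressMessages(stackBoxPredict(f2, sim$dets))
    expect_equal(p1, p2)
    expect_gt(nrow(p1), 0L)
  }
})
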