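# Worked examples use iou(A,B) = 81/119 for A=(0,0,10,10), B=(1,1,11,11)
# (intersection 81, union 200-81) and iou(B,A) = 64/136 for B=(2,2,12,12).

.threeDets <- function() {
  detectionTable("im1", c(0, 1, 20), c(0, 1, 20), c(10, 11, 30), c(10, 11, 30),
                 score = c(0.9, 0.8, 0.7))
}

test_that("NMS suppresses overlapping lower-scoring boxes and nothing else", {
  out <- fuseDetections(.threeDets(), "nms")
  expect_equal(out$score, c(0.9, 0.7))        # B (iou 81/119 > 0.5) removed
  expect_equal(out$x_min, c(0, 20))

  single <- .threeDets()[1, ]
  expect_equal(fuseDetections(single, "nms"), single, ignore_attr = TRUE)

  disjoint <- .threeDets()[c(1, 3), ]
  expect_equal(nrow(fuseDetections(disjoint, "nms")), 2L)
})

test_that("NMS survivors are an unchanged subset with bounded pairwise IoU", {
  set.seed(21)
  for (rep in 1:20) {
    n <- sample(2:8, 1)
    b <- randomIntBoxes(n)
    d <- detectionTable("im", b[, 1], b[, 2], b[, 3], b[, 4], score = runif(n))
    out <- fuseDetections(d, "nms", fusionConfig(iouThreshold = 0.4))
    expect_lte(nrow(out), nrow(d))
    key <- function(x) paste(x$x_min, x$y_min, x$x_max, x$y_max, x$score)
    expect_true(all(key(out) %in% key(d)))
    if (nrow(out) > 1) {
      m <- iouMatrix(out, out)
      expect_true(all(m[upper.tri(m)] <= 0.4))
    }
  }
})

test_that("Soft-NMS decays scores by the stated gaussian and linear rules", {
  d <- .threeDets()[1:2, ]
  iou <- 81 / 119
  g <- fuseDetections(d, "soft-nms-gaussian")
  expect_equal(g$score, c(0.9, 0.8 * exp(-iou^2 / 0.5)))

  lin <- fuseDetections(d, "soft-nms-linear")
  expect_equal(lin$score, c(0.9, 0.8 * (1 - iou)))

  disjoint <- .threeDets()[c(1, 3), ]
  expect_equal(fuseDetections(disjoint, "soft-nms-linear")$score, c(0.9, 0.7))
  expect_equal(fuseDetections(d[1, ], "soft-nms-gaussian")$score, 0.9)
})

test_that("Soft-NMS limiting cases reduce to hard NMS and to identity", {
  d <- .threeDets()
  # score floor at 1 keeps only the top box of each overlap cluster
  hard <- fuseDetections(d, "soft-nms-gaussian",
                         fusionConfig(softScoreThreshold = 0.99999))
  expect_equal(hard$score, c(0.9))
  # huge sigma: gaussian decay ~ 1, scores unchanged
  soft <- fuseDetections(d, "soft-nms-gaussian", fusionConfig(softSigma = 1e9))
  expect_equal(soft$score, d$score, tolerance = 1e-6)
})

test_that("NMW fuses clusters by score*IoU weights and keeps the seed score", {
  single <- .threeDets()[1, ]
  out <- fuseDetections(single, "nmw")
  expect_equal(out$x_min, 0); expect_equal(out$score, 0.9)

  twins <- detectionTable("im", c(3, 3), c(4, 4), c(9, 9), c(9, 9),
                          score = c(0.9, 0.4), model_id = c("a", "b"))
  tw <- fuseDetections(twins, "nmw")
  expect_equal(nrow(tw), 1L)
  expect_equal(c(tw$x_min, tw$y_min, tw$x_max, tw$y_max), c(3, 4, 9, 9))
  expect_equal(tw$score, 0.9)

  pair <- detectionTable("im", c(0, 2), c(0, 2), c(10, 12), c(10, 12),
                         score = c(0.9, 0.6), model_id = c("a", "b"))
  f <- fuseDetections(pair, "nmw", fusionConfig(iouThreshold = 0.3))
  wB <- 0.6 * (64 / 136)
  expect_equal(f$x_min, (0.9 * 0 + wB * 2) / (0.9 + wB))
  expect_equal(f$score, 0.9)
})

test_that("WBF averages coordinates by confidence and confidences per mode", {
  pair <- detectionTable("im", c(0, 2), c(0, 2), c(10, 12), c(10, 12),
                         score = c(0.5, 0.5), model_id = c("a", "b"))
  f <- fuseDetections(pair, "wbf", fusionConfig(iouThreshold = 0.3))
  expect_equal(c(f$x_min, f$y_min, f$x_max, f$y_max), c(1, 1, 11, 11))

  pair2 <- detectionTable("im", c(0, 2), c(0, 2), c(10, 12), c(10, 12),
                          score = c(0.8, 0.4), model_id = c("a", "b"))
  f2 <- fuseDetections(pair2, "wbf", fusionConfig(iouThreshold = 0.3))
  expect_equal(f2$x_min, (0 * 0.8 + 2 * 0.4) / 1.2)
  expect_equal(f2$score, 0.6)  # mean(0.8, 0.4), 2/2 models contribute

  fmax <- fuseDetections(pair2, "wbf-max", fusionConfig(iouThreshold = 0.3))
  expect_equal(fmax$score, 0.8)

  # single model, single box, rescaling off: identity
  one <- pair2[1, ]
  f1 <- fuseDetections(one, "wbf", fusionConfig(wbfRescale = FALSE))
  expect_equal(c(f1$x_min, f1$x_max, f1$score), c(0, 10, 0.8))
  # with rescaling, a one-of-two-models cluster is halved
  f1b <- fuseDetections(one, "wbf", roster = c("a", "b"))
  expect_equal(f1b$score, 0.4)
})

test_that("WBF fused coordinates stay inside the member envelope", {
  set.seed(22)
  for (rep in 1:20) {
    n <- sample(2:8, 1)
    b <- randomIntBoxes(n)
    d <- detectionTable("im", b[, 1], b[, 2], b[, 3], b[, 4], score = runif(n),
                        model_id = sample(c("a", "b"), n, replace = TRUE))
    f <- fuseDetections(d, "wbf", roster = c("a", "b"))
    for (k in seq_len(nrow(f))) {
      mem <- d[f$support[[k]], ]
      expect_gte(f$x_min[k], min(mem$x_min) - 1e-9)
      expect_lte(f$x_max[k], max(mem$x_max) + 1e-9)
      expect_gte(f$y_min[k], min(mem$y_min) - 1e-9)
      expect_lte(f$y_max[k], max(mem$y_max) + 1e-9)
    }
  }
})

test_that("fusion treats images independently", {
  set.seed(23)
  b1 <- randomIntBoxes(5); b2 <- randomIntBoxes(5)
  d1 <- detectionTable("imA", b1[, 1], b1[, 2], b1[, 3], b1[, 4],
                       score = runif(5), model_id = "a")
  d2 <- detectionTable("imB", b2[, 1], b2[, 2], b2[, 3], b2[, 4],
                       score = runif(5), model_id = "a")
  both <- rbind(d1, d2)
  for (m in c("nms", "soft-nms-gaussian", "soft-nms-linear", "nmw", "wbf")) {
    u <- fuseDetections(both, m)
    s <- rbind(fuseDetections(d1, m), fuseDetections(d2, m))
    cols <- c("image_id", "x_min", "y_min", "x_max", "y_max", "score")
    expect_equal(u[order(u$image_id, u$score), cols],
                 s[order(s$image_id, s$score), cols],
                 ignore_attr = TRUE)
  }
})

test_that("NMS and WBF match independent reference implementations", {
  set.seed(24)
  for (rep in 1:100) {
    n <- sample(1:8, 1)
    b <- randomIntBoxes(n)
    scores <- runif(n)
    models <- sample(c("m1", "m2"), n, replace = TRUE)
    d <- detectionTable("im", b[, 1], b[, 2], b[, 3], b[, 4],
                        score = scores, model_id = models)
    thr <- 0.45

    got <- fuseDetections(d, "nms", fusionConfig(iouThreshold = thr))
    want <- nmsOracle(b, scores, thr)
    expect_equal(sort(got$score), sort(scores[want]))

    gotW <- fuseDetections(d, "wbf", fusionConfig(iouThreshold = thr),
                           roster = c("m1", "m2"))
    wantW <- wbfOracle(b, scores, models, 2L, thr)
    om <- order(gotW$score, gotW$x_min)
    ow <- order(wantW[, 5], wantW[, 1])
    expect_equal(unname(as.matrix(gotW[om, c("x_min", "y_min", "x_max", "y_max")])),
                 unname(wantW[ow, 1:4, drop = FALSE]), tolerance = 1e-6)
    expect_equal(gotW$score[om], unname(wantW[ow, 5]), tolerance = 1e-6)
  }
})
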