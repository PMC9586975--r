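# Independent oracles used to cross-check the package implementations.
# Each is written as a direct, slow transcription of the defining rule,
# sharing no code with the package internals.

# Pixel-rasterization IoU for integer-coordinate boxes: count unit cells
# [i, i+1) x [j, j+1) covered by each box.
rasterIoU <- function(a, b) {
  cells <- function(bx) {
    xs <- seq(bx[1], bx[3] - 1L)
    ys <- seq(bx[2], bx[4] - 1L)
    paste(rep(xs, times = length(ys)), rep(ys, each = length(xs)))
  }
  ca <- cells(a); cb <- cells(b)
  inter <- length(intersect(ca, cb))
  inter / (length(ca) + length(cb) - inter)
}

# Closed-form IoU used where rasterization is too slow; kept as plain
# arithmetic on one pair.
pairIoU <- function(a, b) {
  iw <- min(a[3], b[3]) - max(a[1], b[1])
  ih <- min(a[4], b[4]) - max(a[2], b[2])
  if (iw <= 0 || ih <= 0) return(0)
  inter <- iw * ih
  areaA <- (a[3] - a[1]) * (a[4] - a[2])
  areaB <- (b[3] - b[1]) * (b[4] - b[2])
  inter / (areaA + areaB - inter)
}

# Greedy NMS transcribed literally: repeatedly take the highest-scoring
# remaining box, discard all remaining boxes overlapping it above thr.
nmsOracle <- function(boxes, scores, thr) {
  remaining <- order(scores, decreasing = TRUE)
  kept <- integer(0)
  while (length(remaining)) {
    top <- remaining[1L]
    kept <- c(kept, top)
    remaining <- remaining[-1L]
    if (length(remaining)) {
      ov <- vapply(remaining, function(i)
        pairIoU(boxes[top, ], boxes[i, ]), 0)
      remaining <- remaining[ov <= thr]
    }
  }
  sort(kept)
}

# WBF transcribed from the published algorithm: boxes in score order are
# matched against the running fused boxes; the fused box is the
# score-weighted coordinate mean of its cluster, its confidence the cluster
# mean rescaled by (distinct contributing models / total models).
wbfOracle <- function(boxes, scores, models, nModels, thr) {
  ord <- order(scores, decreasing = TRUE)
  clusters <- list()
  for (i in ord) {
    assigned <- FALSE
    if (length(clusters)) {
      ious <- vapply(clusters, function(cl) pairIoU(boxes[i, ], cl$fused), 0)
      k <- which.max(ious)
      if (ious[k] > thr) {
        clusters[[k]]$members <- c(clusters[[k]]$members, i)
        m <- clusters[[k]]$members
        clusters[[k]]$fused <-
          colSums(boxes[m, , drop = FALSE] * scores[m]) / sum(scores[m])
        assigned <- TRUE
      }
    }
    if (!assigned)
      clusters[[length(clusters) + 1L]] <- list(fused = boxes[i, ], members = i)
  }
  do.call(rbind, lapply(clusters, function(cl) {
    conf <- mean(scores[cl$members]) *
      min(length(unique(models[cl$members])), nModels) / nModels
    c(cl$fused, conf)
  }))
}

# Brute-force 101-point AP: for every recall grid point scan every prefix of
# the ranked detection list for the best precision at recall >= r.
apOracle <- function(tp, nGt) {
  if (nGt == 0) return(NA_real_)
  if (!length(tp)) return(0)
  prec <- recall <- numeric(length(tp))
  for (i in seq_along(tp)) {
    prec[i] <- sum(tp[1:i]) / i
    recall[i] <- sum(tp[1:i]) / nGt
  }
  total <- 0
  for (r in seq(0, 1, by = 0.01)) {
    best <- 0
    for (i in seq_along(tp)) if (recall[i] >= r && prec[i] > best) best <- prec[i]
    total <- total + best
  }
  total / 101
}

# Greedy TP labelling for one image, transcribed from the evaluation rule:
# detections in confidence order take the unmatched GT with highest IoU >= thr.
labelOracle <- function(gtBoxes, detBoxes, detScores, thr) {
  ord <- order(detScores, decreasing = TRUE)
  used <- rep(FALSE, nrow(gtBoxes))
  tp <- logical(length(ord))
  for (j in seq_along(ord)) {
    d <- ord[j]
    best <- 0; bestG <- NA
    for (g in seq_len(nrow(gtBoxes))) {
      if (used[g]) next
      v <- pairIoU(detBoxes[d, ], gtBoxes[g, ])
      if (v >= thr && v > best) { best <- v; bestG <- g }
    }
    if (!is.na(bestG)) { used[bestG] <- TRUE; tp[j] <- TRUE }
  }
  tp
}

# Random valid integer-coordinate boxes inside a widthxheight canvas.
randomIntBoxes <- function(n, width = 50L, height = 50L) {
  x1 <- sample.int(width - 1L, n, replace = TRUE) - 1L
  y1 <- sample.int(height - 1L, n, replace = TRUE) - 1L
  w <- vapply(x1, function(v) sample.int(width - v, 1L), 0L)
  h <- vapply(y1, function(v) sample.int(height - v, 1L), 0L)
  cbind(x_min = x1, y_min = y1, x_max = x1 + w, y_max = y1 + h)
}

# A small deterministic 3-model fixture: two ground truths, model "b" misses
# the first GT, and a third GT no model detects.
fillRuleFixture <- function() {
  gts <- groundTruthTable("im1", c(10, 200, 400), c(10, 200, 400),
                          c(110, 300, 460), c(110, 300, 460))
  dets <- rbind(
    detectionTable("im1", 12, 12, 112, 112, 0.9, "a"),   # gt1, iou high
    detectionTable("im1", 20, 20, 115, 115, 0.8, "c"),   # gt1, iou lower
    detectionTable("im1", 201, 201, 301, 301, 0.7, "a"), # gt2
    detectionTable("im1", 199, 199, 299, 299, 0.6, "b"), # gt2
    detectionTable("im1", 202, 202, 302, 302, 0.5, "c")) # gt2
  list(gts = gts, dets = dets, roster = c("a", "b", "c"))
}
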