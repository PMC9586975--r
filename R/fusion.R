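#' @include AllClasses.R
NULL

# Stable processing order within one image/class group:
# confidence descending, then roster position, then input order.
.fusionOrder <- function(scores, model_id, roster) {
  order(-scores, match(model_id, roster), seq_along(scores))
}

.splitGroups <- function(dets) {
  split(seq_len(nrow(dets)),
        interaction(dets$image_id, dets$class_id, drop = TRUE, lex.order = TRUE))
}

#' Fuse pooled detections with a classical box-fusion baseline
#'
#' Applies one of the comparison ensemble algorithms independently per image
#' and per class: greedy non-maximum suppression (\code{"nms"}), Soft-NMS
#' with Gaussian or linear score decay, non-maximum weighted fusion
#' (\code{"nmw"}) or weighted boxes fusion (\code{"wbf"}, and its
#' maximum-confidence variant \code{"wbf-max"}).
#'
#' NMS keeps the highest-scoring box of every overlap group and discards
#' boxes whose IoU with a kept box exceeds the threshold; survivors are
#' returned unchanged.  Soft-NMS instead decays the scores of overlapping
#' boxes — by \eqn{s\,e^{-\mathrm{IoU}^2/\sigma}} (Gaussian) or by
#' \eqn{s\,(1-\mathrm{IoU})} when the IoU exceeds the threshold (linear) —
#' and removes boxes whose decayed score falls below
#' \code{softScoreThreshold}.  NMW averages each overlap cluster's
#' coordinates with weights \eqn{w_i = s_i \cdot \mathrm{IoU}(b_i,
#' \mathrm{seed})} and keeps the seed's confidence unchanged.  WBF clusters
#' incrementally against the running fused box, averages coordinates with
#' the confidences as weights, sets the fused confidence to the cluster mean
#' (or maximum for \code{"wbf-max"}) and, by default, rescales it by the
#' fraction of base learners contributing to the cluster.
#'
#' @param dets detection table (see [detectionTable()]); may span several
#'   images and classes.
#' @param method one of \code{"nms"}, \code{"soft-nms-gaussian"},
#'   \code{"soft-nms-linear"}, \code{"nmw"}, \code{"wbf"}, \code{"wbf-max"}.
#' @param config a [FusionConfig-class]; \code{fusionConfig()} defaults
#'   otherwise.
#' @param roster ordered base-learner identifiers; defaults to the order of
#'   first appearance in \code{dets}.  Fixes tie-breaking and, for WBF, the
#'   model count used in confidence rescaling.
#' @return a detection table.  For \code{nmw}/\code{wbf} the rows are fused
#'   boxes (model_id \code{"fused"}) with a \code{support} list-column of
#'   contributing input row indices.
#' @examples
#' d <- detectionTable("im1", c(0, 1, 20), c(0, 1, 20), c(10, 11, 30),
#'                     c(10, 11, 30), score = c(0.9, 0.8, 0.7))
#' fuseDetections(d, "nms")            # drops the second box
#' fuseDetections(d, "wbf")$support
#' @export
fuseDetections <- function(dets,
                           method = c("nms", "soft-nms-gaussian",
                                      "soft-nms-linear", "nmw", "wbf",
                                      "wbf-max"),
                           config = fusionConfig(), roster = NULL) {
  method <- match.arg(method)
  .assertDetections(dets)
  stopifnot(is(config, "FusionConfig"))
  if (is.null(roster)) roster <- unique(dets$model_id)
  if (length(config@modelWeights)) {
    if (is.null(names(config@modelWeights)) ||
        !all(roster %in% names(config@modelWeights)))
      stop("modelWeights must be named and cover every roster model")
  }
  if (nrow(dets) == 0L) return(dets)
  groups <- .splitGroups(dets)
  out <- lapply(groups, function(idx) {
    g <- dets[idx, , drop = FALSE]
    switch(method,
      "nms" = g[.nmsKeep(g, config@iouThreshold, roster), , drop = FALSE],
      "soft-nms-gaussian" = .softNms(g, config, roster, "gaussian"),
      "soft-nms-linear"   = .softNms(g, config, roster, "linear"),
      "nmw" = .nmw(g, config, roster, idx),
      "wbf" = .wbf(g, config, roster, idx, confMode = "average"),
      "wbf-max" = .wbf(g, config, roster, idx, confMode = "maximum"))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# indices (into g) surviving greedy NMS
.nmsKeep <- function(g, thr, roster) {
  ord <- .fusionOrder(g$score, g$model_id, roster)
  boxes <- .boxMatrix(g)
  keep <- integer(0)
  alive <- ord
  while (length(alive)) {
    top <- alive[1L]
    keep <- c(keep, top)
    alive <- alive[-1L]
    if (length(alive)) {
      ious <- boxIoU(boxes[rep(top, length(alive)), , drop = FALSE],
                     boxes[alive, , drop = FALSE])
      alive <- alive[ious <= thr]
    }
  }
  sort(keep)
}

.softNms <- function(g, config, roster, mode) {
  boxes <- .boxMatrix(g)
  cur <- g$score
  alive <- seq_len(nrow(g))
  keptIdx <- integer(0); keptScore <- numeric(0)
  while (length(alive)) {
    o <- .fusionOrder(cur[alive], g$model_id[alive], roster)
    top <- alive[o[1L]]
    keptIdx <- c(keptIdx, top)
    keptScore <- c(keptScore, cur[top])
    alive <- setdiff(alive, top)
    if (length(alive)) {
      ious <- boxIoU(boxes[rep(top, length(alive)), , drop = FALSE],
                     boxes[alive, , drop = FALSE])
      decay <- if (mode == "gaussian") exp(-ious^2 / config@softSigma)
               else ifelse(ious > config@iouThreshold, 1 - ious, 1)
      cur[alive] <- cur[alive] * decay
      alive <- alive[cur[alive] >= config@softScoreThreshold]
    }
  }
  res <- g[keptIdx, , drop = FALSE]
  res$score <- keptScore
  res[order(keptIdx), , drop = FALSE]
}

# greedy seed clustering: member joins the first (highest-score) seed with
# IoU > threshold; fused box is the s*IoU-weighted coordinate mean, fused
# confidence is the seed's (scores are not changed by NMW)
.nmw <- function(g, config, roster, globalIdx) {
  ord <- .fusionOrder(g$score, g$model_id, roster)
  boxes <- .boxMatrix(g)
  seeds <- integer(0)
  members <- list()
  for (i in ord) {
    placed <- FALSE
    for (k in seq_along(seeds)) {
      if (boxIoU(boxes[i, ], boxes[seeds[k], ]) > config@iouThreshold) {
        members[[k]] <- c(members[[k]], i); placed <- TRUE; break
      }
    }
    if (!placed) { seeds <- c(seeds, i); members[[length(seeds)]] <- i }
  }
  fused <- lapply(seq_along(seeds), function(k) {
    m <- members[[k]]
    w <- g$score[m] * boxIoU(boxes[m, , drop = FALSE],
                             boxes[rep(seeds[k], length(m)), , drop = FALSE])
    coords <- colSums(boxes[m, , drop = FALSE] * w) / sum(w)
    data.frame(image_id = g$image_id[1L], class_id = g$class_id[1L],
               x_min = coords[1L], y_min = coords[2L],
               x_max = coords[3L], y_max = coords[4L],
               score = g$score[seeds[k]], model_id = "fused")
  })
  res <- do.call(rbind, fused)
  res$support <- I(lapply(members, function(m) globalIdx[m]))
  res
}

.wbf <- function(g, config, roster, globalIdx, confMode) {
  w <- if (length(config@modelWeights)) config@modelWeights[roster]
       else setNames(rep(1, length(roster)), roster)
  ord <- .fusionOrder(g$score, g$model_id, roster)
  boxes <- .boxMatrix(g)
  scores <- g$score * w[g$model_id]
  fusedBox <- list(); members <- list()
  for (i in ord) {
    best <- 0; bestK <- 0L
    for (k in seq_along(fusedBox)) {
      iou <- boxIoU(boxes[i, ], fusedBox[[k]])
      if (iou > best) { best <- iou; bestK <- k }
    }
    if (bestK > 0L && best > config@iouThreshold) {
      members[[bestK]] <- c(members[[bestK]], i)
      m <- members[[bestK]]
      fusedBox[[bestK]] <- colSums(boxes[m, , drop = FALSE] * scores[m]) /
        sum(scores[m])
    } else {
      fusedBox[[length(fusedBox) + 1L]] <- boxes[i, ]
      members[[length(members) + 1L]] <- i
    }
  }
  fused <- lapply(seq_along(fusedBox), function(k) {
    m <- members[[k]]
    conf <- if (confMode == "average") mean(g$score[m]) else max(g$score[m])
    if (config@wbfRescale)
      conf <- conf * min(length(unique(g$model_id[m])), length(roster)) /
        length(roster)
    b <- fusedBox[[k]]
    data.frame(image_id = g$image_id[1L], class_id = g$class_id[1L],
               x_min = b[1L], y_min = b[2L], x_max = b[3L], y_max = b[4L],
               score = conf, model_id = "fused")
  })
  res <- do.call(rbind, fused)
  res$support <- I(lapply(members, function(m) globalIdx[m]))
  res
}
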