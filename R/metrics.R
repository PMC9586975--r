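#' @include AllClasses.R
NULL

.IOU_GRID <- seq(0.5, 0.95, by = 0.05)

# Per image/class evaluation context, computed once and reused across IoU
# thresholds, area ranges and detection caps: detections sorted by score
# (descending, stable) with their IoU matrix against the group's GTs.
.evalGroups <- function(gts, dets) {
  gtKey <- paste(gts$image_id, gts$class_id)
  detKey <- paste(dets$image_id, dets$class_id)
  keys <- unique(c(gtKey, detKey))
  lapply(setNames(nm = keys), function(key) {
    gi <- which(gtKey == key)
    di <- which(detKey == key)
    di <- di[order(-dets$score[di], di)]
    g <- list(gtArea = boxArea(gts[gi, , drop = FALSE]),
              detArea = boxArea(dets[di, , drop = FALSE]),
              score = dets$score[di],
              iou = iouMatrix(dets[di, , drop = FALSE],
                              gts[gi, , drop = FALSE]))
    g
  })
}

# Greedy one-to-one matching of one prepared group at one IoU threshold.
# gtIgnore/detIgnore implement the COCO area-range convention: out-of-range
# GTs may still absorb detections, but neither they nor detections matched
# to them (or unmatched out-of-range detections) count towards TP/FP/nGt.
.greedyMatch <- function(g, thr, areaRange = NULL, maxDets = Inf) {
  nD <- length(g$score); nG <- length(g$gtArea)
  keepD <- seq_len(min(nD, maxDets))
  gtIgnore <- if (is.null(areaRange)) rep(FALSE, nG)
              else g$gtArea < areaRange[1] | g$gtArea >= areaRange[2]
  tp <- logical(length(keepD))
  detIgnore <- logical(length(keepD))
  matched <- logical(nG)
  for (d in seq_along(keepD)) {
    ious <- if (nG) g$iou[keepD[d], ] else numeric(0)
    cand <- which(!matched & ious >= thr)
    hit <- NA_integer_
    if (length(cand)) {
      real <- cand[!gtIgnore[cand]]
      if (length(real)) hit <- real[which.max(ious[real])]
      else hit <- cand[which.max(ious[cand])]
    }
    if (!is.na(hit)) {
      matched[hit] <- TRUE
      if (gtIgnore[hit]) detIgnore[d] <- TRUE else tp[d] <- TRUE
    } else if (!is.null(areaRange)) {
      a <- g$detArea[keepD[d]]
      if (a < areaRange[1] || a >= areaRange[2]) detIgnore[d] <- TRUE
    }
  }
  list(score = g$score[keepD], tp = tp, detIgnore = detIgnore,
       nGt = sum(!gtIgnore))
}

# Pool matched labels over groups for one (threshold, area, maxDets) setting.
.pooledLabels <- function(groups, thr, areaRange = NULL, maxDets = Inf) {
  parts <- lapply(groups, .greedyMatch, thr = thr, areaRange = areaRange,
                  maxDets = maxDets)
  list(score = unlist(lapply(parts, `[[`, "score"), use.names = FALSE),
       tp = unlist(lapply(parts, `[[`, "tp"), use.names = FALSE),
       detIgnore = unlist(lapply(parts, `[[`, "detIgnore"), use.names = FALSE),
       nGt = sum(vapply(parts, `[[`, 0, "nGt")))
}

#' Label detections as true or false positives
#'
#' Standard greedy evaluation matching: detections are taken in decreasing
#' confidence order; each claims the still-unmatched same-image, same-class
#' ground truth with the highest IoU at or above the threshold (ties to the
#' first ground truth), or is a false positive; each ground truth is matched
#' at most once.
#'
#' @param gts ground-truth table.
#' @param dets detection table.
#' @param iouThreshold matching threshold.
#' @return data frame, one row per detection in decreasing-confidence order
#'   (grouped by image/class): \code{score}, logical \code{tp}.
#' @export
matchForEval <- function(gts, dets, iouThreshold = 0.5) {
  .assertGroundTruth(gts); .assertDetections(dets)
  lab <- .pooledLabels(.evalGroups(gts, dets), iouThreshold)
  o <- order(-lab$score)
  data.frame(score = lab$score[o], tp = lab$tp[o])
}

#' 101-point interpolated average precision
#'
#' Precision is interpolated as the maximum precision at any recall at or
#' above \eqn{r}, evaluated on the grid \eqn{r \in \{0, 0.01, \ldots, 1\}},
#' and averaged over the 101 points.
#'
#' @param tp logical vector of true-positive labels, ordered by decreasing
#'   confidence.
#' @param nGt number of ground truths (recall denominator).
#' @return scalar AP, or \code{NA} when \code{nGt} is 0.
#' @export
averagePrecision101 <- function(tp, nGt) {
  if (nGt == 0L) return(NA_real_)
  if (!length(tp)) return(0)
  cumTp <- cumsum(tp)
  precision <- cumTp / seq_along(tp)
  recall <- cumTp / nGt
  # running max of precision from the right = interpolated precision
  interp <- rev(cummax(rev(precision)))
  grid <- seq(0, 1, by = 0.01)
  idx <- findInterval(grid, recall, left.open = TRUE) + 1L
  p <- ifelse(idx <= length(tp), interp[pmin(idx, length(tp))], 0)
  mean(p)
}

.apAt <- function(groups, thr, areaRange = NULL, maxDets = Inf) {
  lab <- .pooledLabels(groups, thr, areaRange, maxDets)
  o <- order(-lab$score)
  keep <- !lab$detIgnore[o]
  averagePrecision101(lab$tp[o][keep], lab$nGt)
}

.recallAt <- function(groups, thr, areaRange = NULL, maxDets = Inf) {
  lab <- .pooledLabels(groups, thr, areaRange, maxDets)
  if (lab$nGt == 0L) return(NA_real_)
  sum(lab$tp) / lab$nGt
}

#' Average recall over the IoU grid
#'
#' Recall at each IoU threshold in .5:.05:.95, averaged, with detections
#' truncated per image to the \code{maxDets} most confident before matching.
#'
#' @inheritParams matchForEval
#' @param maxDets per-image detection cap (1 and 10 give the AR_1 and AR_10
#'   headline numbers; 100 is the COCO default for bucketed AR).
#' @param areaRange optional \code{c(lo, hi)} ground-truth area bucket in
#'   squared pixels.
#' @return scalar AR, or \code{NA} when the bucket holds no ground truths.
#' @export
averageRecall <- function(gts, dets, maxDets = 1, areaRange = NULL) {
  .assertGroundTruth(gts); .assertDetections(dets)
  groups <- .evalGroups(gts, dets)
  r <- vapply(.IOU_GRID, function(thr)
    .recallAt(groups, thr, areaRange, maxDets), 0)
  if (all(is.na(r))) NA_real_ else mean(r)
}

#' Evaluate detections against ground truths
#'
#' Computes the ten headline detection metrics: AP averaged over the IoU
#' grid .5:.05:.95, AP at IoU .50 and .75, AP restricted to medium and
#' large ground truths (COCO area buckets), average recall at 1 and 10
#' detections per image, bucketed AR (at 100 detections per image), and
#' mAP@.50, the per-class mean of AP@.50.  All are computed per class and
#' averaged over classes with at least one ground truth.  Buckets without
#' ground truths yield \code{NA}.
#'
#' @inheritParams matchForEval
#' @param sizeThresholds lower edges of the medium and large area buckets in
#'   squared pixels (COCO convention: \code{c(32^2, 96^2)}).
#' @param maxDets per-image cap for the AP metrics and bucketed AR.
#' @return a [MetricsReport-class].
#' @examples
#' gt <- groundTruthTable("im1", 10, 10, 110, 110)
#' det <- detectionTable("im1", 10, 10, 110, 110, score = 0.9)
#' metricValues(evaluateDetections(gt, det))
#' @export
evaluateDetections <- function(gts, dets, sizeThresholds = c(32^2, 96^2),
                               maxDets = 100) {
  .assertGroundTruth(gts); .assertDetections(dets)
  if (nrow(gts) == 0L) stop("cannot evaluate against an empty ground-truth set")
  medium <- c(sizeThresholds[1], sizeThresholds[2])
  large <- c(sizeThresholds[2], Inf)
  classes <- sort(unique(gts$class_id))
  perClass <- lapply(classes, function(cl) {
    g <- gts[gts$class_id == cl, , drop = FALSE]
    d <- dets[dets$class_id == cl, , drop = FALSE]
    groups <- .evalGroups(g, d)
    apGrid <- vapply(.IOU_GRID, function(t) .apAt(groups, t, maxDets = maxDets), 0)
    apMed <- vapply(.IOU_GRID, function(t) .apAt(groups, t, medium, maxDets), 0)
    apLar <- vapply(.IOU_GRID, function(t) .apAt(groups, t, large, maxDets), 0)
    arAt <- function(md, ar = NULL) {
      r <- vapply(.IOU_GRID, function(t) .recallAt(groups, t, ar, md), 0)
      if (all(is.na(r))) NA_real_ else mean(r)
    }
    c(ap_range = mean(apGrid), ap_50 = apGrid[1L],
      ap_75 = apGrid[which(abs(.IOU_GRID - 0.75) < 1e-9)],
      ap_medium = if (all(is.na(apMed))) NA_real_ else mean(apMed),
      ap_large = if (all(is.na(apLar))) NA_real_ else mean(apLar),
      ar_1 = arAt(1), ar_10 = arAt(10),
      ar_medium = arAt(maxDets, medium), ar_large = arAt(maxDets, large),
      map_50 = apGrid[1L])
  })
  m <- do.call(rbind, perClass)
  vals <- apply(m, 2L, function(col)
    if (all(is.na(col))) NA_real_ else mean(col, na.rm = TRUE))
  names(vals) <- .METRIC_NAMES
  new("MetricsReport", values = vals, nGroundTruth = nrow(gts),
      nDetections = as.integer(nrow(dets)))
}

#' Summarise metrics reports over cross-validation folds
#'
#' @param reports list of [MetricsReport-class] objects, one per fold.
#' @return data frame with one row per metric: \code{metric}, \code{mean},
#'   \code{sd} (sample standard deviation over folds).
#' @examples
#' # two folds with mAP@.50 of 0.5 and 0.7 average to 0.60 +/- 0.14
#' @export
crossvalSummary <- function(reports) {
  if (length(reports) < 2L)
    stop("need at least two folds to summarise")
  stopifnot(all(vapply(reports, is, TRUE, "MetricsReport")))
  m <- do.call(rbind, lapply(reports, metricValues))
  data.frame(metric = .METRIC_NAMES,
             mean = apply(m, 2L, mean, na.rm = TRUE),
             sd = apply(m, 2L, sd, na.rm = TRUE),
             row.names = NULL)
}

#' Format cross-validation summaries as a markdown table
#'
#' Lays out one row per algorithm and one \code{mean ± sd} column per
#' metric, mirroring the usual precision/recall comparison tables.
#'
#' @param summaries named list of [crossvalSummary()] data frames, one per
#'   algorithm.
#' @param digits decimal places (default 2).
#' @return character vector of markdown lines.
#' @export
formatMetricsTable <- function(summaries, digits = 2) {
  stopifnot(length(summaries) >= 1L)
  cols <- summaries[[1L]]$metric
  header <- paste0("| Algorithm | ", paste(cols, collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", length(cols) + 1L), collapse = "|"), "|")
  rows <- vapply(names(summaries), function(nm) {
    s <- summaries[[nm]]
    cells <- sprintf(paste0("%.", digits, "f ± %.", digits, "f"),
                     s$mean, s$sd)
    cells[is.na(s$mean)] <- "--"
    paste0("| ", nm, " | ", paste(cells, collapse = " | "), " |")
  }, "")
  c(header, sep, unname(rows))
}
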