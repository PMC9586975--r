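#' @include train.R fusion.R
NULL

#' Assemble test-time pseudo-ground-truth rows
#'
#' At test time no ground truth exists, so every base learner's predictions
#' are treated as the ground truth in turn: for each anchor detection the
#' best-IoU detection of each remaining model is found (IoU must exceed
#' \code{minIou}); anchors no other model supports are dropped; remaining
#' empty slots are filled with the row's highest-IoU match, exactly as in
#' training.  The anchor occupies its own model's slot, so each row carries
#' \eqn{M} predictor boxes.  Rows from all anchor models are concatenated.
#'
#' @param dets pooled detection table over the roster models.
#' @param roster ordered base-learner identifiers (must match the fitted
#'   model's roster when used for prediction).
#' @param minIou availability cutoff, as in [matchToGroundTruth()].
#' @return a \code{pseudoRows} list: \code{roster}; matrices \code{coords}
#'   (n x 4M, slot-major, columns \code{<model>.<coordinate>}),
#'   \code{conf} (n x M slot confidences) and \code{fillFlags}; vectors
#'   \code{image_id}, \code{class_id}, \code{anchorModel}.
#' @export
assembleTestRows <- function(dets, roster = NULL, minIou = 0) {
  .assertDetections(dets)
  if (is.null(roster)) roster <- unique(dets$model_id)
  if (!all(dets$model_id %in% roster))
    stop("detections contain model(s) absent from the roster")
  M <- length(roster)
  rows <- lapply(seq_along(roster), function(a) {
    anchorIdx <- which(dets$model_id == roster[a])
    if (!length(anchorIdx)) return(NULL)
    anchors <- dets[anchorIdx, , drop = FALSE]
    others <- dets[dets$model_id != roster[a], , drop = FALSE]
    mt <- matchToGroundTruth(anchors[.GT_COLS], others,
                             roster = setdiff(roster, roster[a]),
                             minIou = minIou)
    # an anchor with zero matches from the remaining models is dropped
    mt <- imputeAndFilter(mt)
    if (!nrow(mt$gt)) return(NULL)
    n <- nrow(mt$gt)
    detIdxFull <- matrix(NA_integer_, n, M, dimnames = list(NULL, roster))
    fill <- matrix(FALSE, n, M, dimnames = list(NULL, roster))
    detIdxFull[, setdiff(roster, roster[a])] <- mt$detIdx
    fill[, setdiff(roster, roster[a])] <- mt$fillFlags
    otherBox <- .boxMatrix(others)
    coords <- matrix(NA_real_, n, 4L * M)
    conf <- matrix(NA_real_, n, M, dimnames = list(NULL, roster))
    keptAnchors <- anchorIdx[mt$keptRows]
    for (m in seq_len(M)) {
      cols <- (m - 1L) * 4L + 1:4
      if (roster[m] == roster[a]) {
        coords[, cols] <- .boxMatrix(dets[keptAnchors, , drop = FALSE])
        conf[, m] <- dets$score[keptAnchors]
      } else {
        coords[, cols] <- otherBox[detIdxFull[, m], , drop = FALSE]
        conf[, m] <- others$score[detIdxFull[, m]]
      }
    }
    colnames(coords) <- paste(rep(roster, each = 4L), .BOX_COLS, sep = ".")
    list(coords = coords, conf = conf, fillFlags = fill,
         image_id = dets$image_id[keptAnchors],
         class_id = dets$class_id[keptAnchors],
         anchorModel = rep(roster[a], n))
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows))
    return(list(roster = roster,
                coords = matrix(numeric(0), 0, 4L * M),
                conf = matrix(numeric(0), 0, M),
                fillFlags = matrix(logical(0), 0, M),
                image_id = character(0), class_id = integer(0),
                anchorModel = character(0)))
  list(roster = roster,
       coords = do.call(rbind, lapply(rows, `[[`, "coords")),
       conf = do.call(rbind, lapply(rows, `[[`, "conf")),
       fillFlags = do.call(rbind, lapply(rows, `[[`, "fillFlags")),
       image_id = unlist(lapply(rows, `[[`, "image_id"), use.names = FALSE),
       class_id = unlist(lapply(rows, `[[`, "class_id"), use.names = FALSE),
       anchorModel = unlist(lapply(rows, `[[`, "anchorModel"),
                            use.names = FALSE))
}

#' Remove duplicated pseudo-ground-truth rows
#'
#' Symmetric anchor matching of identical detections produces rows whose
#' full 4M-coordinate slot tuple coincides exactly; only the first
#' occurrence (per image and class) is kept.  Equality is exact, not
#' tolerance-based: duplicates arise from copying the very same detections
#' into different anchors' rows.
#'
#' @param rows output of [assembleTestRows()].
#' @return the same structure with duplicated rows removed.
#' @export
deduplicateRows <- function(rows) {
  if (!nrow(rows$coords)) return(rows)
  key <- paste(rows$image_id, rows$class_id,
               apply(rows$coords, 1L, paste, collapse = "|"))
  keep <- !duplicated(key)
  rows$coords <- rows$coords[keep, , drop = FALSE]
  rows$conf <- rows$conf[keep, , drop = FALSE]
  rows$fillFlags <- rows$fillFlags[keep, , drop = FALSE]
  rows$image_id <- rows$image_id[keep]
  rows$class_id <- rows$class_id[keep]
  rows$anchorModel <- rows$anchorModel[keep]
  rows
}

#' Predict refined boxes from assembled rows
#'
#' Applies the four fitted coordinate regressors to the slot coordinates of
#' each row, producing one refined box per row.  Predictions that come out
#' degenerate (\code{min >= max} on either axis) are dropped with a message.
#' The meta-regression predicts coordinates only, so the confidence of a
#' stacked box is assembled from its row's slot confidences: their mean by
#' default, or their maximum.
#'
#' @param model a fitted [StackBoxModel-class].
#' @param rows deduplicated output of [assembleTestRows()].
#' @param confMode \code{"mean"} (default) or \code{"max"}.
#' @return a detection table with \code{model_id = "stackbox"}.
#' @export
predictBoxes <- function(model, rows, confMode = c("mean", "max")) {
  confMode <- match.arg(confMode)
  stopifnot(is(model, "StackBoxModel"))
  if (!identical(rows$roster, model@roster))
    stop("row roster does not match the fitted model's roster")
  n <- nrow(rows$coords)
  if (!n)
    return(detectionTable(character(0), numeric(0), numeric(0), numeric(0),
                          numeric(0), numeric(0), model_id = character(0),
                          class_id = integer(0)))
  backend <- .regressorBackends[[model@regressorKind]]
  pred <- sapply(.BOX_COLS, function(coord) {
    cols <- paste(model@roster, coord, sep = ".")
    X <- rows$coords[, cols, drop = FALSE]
    colnames(X) <- model@roster
    backend$predict(model@models[[coord]], X)
  })
  pred <- matrix(pred, nrow = n, dimnames = list(NULL, .BOX_COLS))
  conf <- if (confMode == "mean") rowMeans(rows$conf)
          else apply(rows$conf, 1L, max)
  ok <- pred[, "x_min"] < pred[, "x_max"] & pred[, "y_min"] < pred[, "y_max"]
  if (any(!ok))
    message(sum(!ok), " degenerate predicted box(es) dropped")
  detectionTable(rows$image_id[ok],
                 pred[ok, "x_min"], pred[ok, "y_min"],
                 pred[ok, "x_max"], pred[ok, "y_max"],
                 score = conf[ok], model_id = "stackbox",
                 class_id = rows$class_id[ok])
}

#' Final redundancy removal
#'
#' The stacked predictions inherit one row per surviving anchor, so several
#' near-identical refined boxes can describe the same object.  A last
#' greedy NMS pass per image and class removes boxes overlapping a
#' higher-confidence box with IoU above 0.5, keeping the most confident.
#'
#' @param dets detection table.
#' @param iouThreshold suppression threshold (default 0.5).
#' @return the surviving detections.
#' @export
finalizeDetections <- function(dets, iouThreshold = 0.5) {
  if (!nrow(dets)) return(dets)
  fuseDetections(dets, "nms", fusionConfig(iouThreshold = iouThreshold))
}

#' Run the full test-time stacking pipeline
#'
#' Convenience wrapper: [assembleTestRows()] with the fitted model's roster,
#' [deduplicateRows()], [predictBoxes()] and [finalizeDetections()].
#'
#' @inheritParams predictBoxes
#' @param dets pooled base-learner detection table.
#' @param minIou availability cutoff used during row assembly.
#' @param iouThreshold final NMS threshold (default 0.5).
#' @return a detection table of refined, deduplicated detections.
#' @export
stackBoxPredict <- function(model, dets, confMode = "mean", minIou = 0,
                            iouThreshold = 0.5) {
  rows <- assembleTestRows(dets, roster = model@roster, minIou = minIou)
  rows <- deduplicateRows(rows)
  out <- predictBoxes(model, rows, confMode)
  finalizeDetections(out, iouThreshold)
}
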