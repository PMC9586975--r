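#' @include AllClasses.R
NULL

#' Match base-learner detections to ground truths
#'
#' For every ground truth and every base learner independently, finds the
#' same-image, same-class detection with the highest IoU, provided that IoU
#' exceeds \code{minIou}; the slot is left empty otherwise.  Matching is
#' non-exclusive by default: one detection may serve several ground truths.
#' With \code{exclusive = TRUE} a greedy one-to-one assignment is used
#' instead (ground truths processed in input order, each taking the best
#' still-unclaimed detection of that model).
#'
#' @param gts ground-truth table (see [groundTruthTable()]).
#' @param dets detection table covering the roster models.
#' @param roster ordered base-learner identifiers; defaults to the order of
#'   first appearance in \code{dets}.
#' @param minIou availability cutoff: a detection counts as a match only if
#'   its IoU with the ground truth is strictly greater (default 0).
#' @param exclusive logical; greedy one-to-one assignment per model.
#' @return a \code{matchTable} list: \code{gt} (the input rows), \code{roster},
#'   and two \code{nrow(gts)} by \code{length(roster)} matrices \code{detIdx}
#'   (row indices into \code{dets}, \code{NA} = no match) and \code{iou}.
#' @export
matchToGroundTruth <- function(gts, dets, roster = NULL, minIou = 0,
                               exclusive = FALSE) {
  .assertGroundTruth(gts); .assertDetections(dets)
  if (is.null(roster)) roster <- unique(dets$model_id)
  if (!all(dets$model_id %in% roster))
    stop("detections contain model(s) absent from the roster: ",
         paste(setdiff(unique(dets$model_id), roster), collapse = ", "))
  nG <- nrow(gts); M <- length(roster)
  detIdx <- matrix(NA_integer_, nG, M, dimnames = list(NULL, roster))
  iou <- matrix(NA_real_, nG, M, dimnames = list(NULL, roster))
  if (nG && nrow(dets)) {
    gtKey <- paste(gts$image_id, gts$class_id)
    detKey <- paste(dets$image_id, dets$class_id)
    for (key in unique(gtKey)) {
      gi <- which(gtKey == key)
      for (m in seq_along(roster)) {
        di <- which(detKey == key & dets$model_id == roster[m])
        if (!length(di)) next
        mat <- iouMatrix(gts[gi, , drop = FALSE], dets[di, , drop = FALSE])
        if (exclusive) {
          taken <- logical(length(di))
          for (r in seq_along(gi)) {
            cand <- which(!taken & mat[r, ] > minIou)
            if (!length(cand)) next
            best <- cand[which.max(mat[r, cand])]
            detIdx[gi[r], m] <- di[best]; iou[gi[r], m] <- mat[r, best]
            taken[best] <- TRUE
          }
        } else {
          best <- max.col(mat, ties.method = "first")
          hit <- mat[cbind(seq_along(gi), best)] > minIou
          detIdx[gi[hit], m] <- di[best[hit]]
          iou[gi[hit], m] <- mat[cbind(seq_along(gi), best)][hit]
        }
      }
    }
  }
  structure(list(gt = gts, roster = roster, detIdx = detIdx, iou = iou,
                 dets = dets),
            class = "matchTable")
}

#' Impute missing slots and drop unmatched rows
#'
#' Rows whose every slot is empty are removed (a ground truth no base
#' learner found is not usable for the meta-regression).  In the remaining
#' rows, each empty slot is filled with a copy of the row's highest-IoU
#' matched detection, regardless of which model produced it; ties go to the
#' earlier roster model.  \code{fillFlags} records which slots were imputed.
#'
#' @param mt a \code{matchTable} from [matchToGroundTruth()].
#' @return the \code{matchTable} with empty slots filled, rows with no match
#'   dropped, plus a \code{fillFlags} logical matrix and \code{keptRows}, the
#'   retained ground-truth row indices.
#' @export
imputeAndFilter <- function(mt) {
  stopifnot(inherits(mt, "matchTable"))
  nMatch <- rowSums(!is.na(mt$detIdx))
  keep <- which(nMatch > 0L)
  detIdx <- mt$detIdx[keep, , drop = FALSE]
  iou <- mt$iou[keep, , drop = FALSE]
  fill <- is.na(detIdx)
  if (nrow(detIdx)) {
    # earlier roster model wins IoU ties
    bestSlot <- apply(iou, 1L, function(r) which.max(replace(r, is.na(r), -1)))
    for (j in seq_len(ncol(detIdx))) {
      miss <- which(fill[, j])
      if (length(miss)) {
        detIdx[miss, j] <- detIdx[cbind(miss, bestSlot[miss])]
        iou[miss, j] <- iou[cbind(miss, bestSlot[miss])]
      }
    }
  }
  out <- mt
  out$gt <- mt$gt[keep, , drop = FALSE]
  out$detIdx <- detIdx; out$iou <- iou
  out$fillFlags <- fill
  out$keptRows <- keep
  out
}

#' Build the four per-coordinate regression datasets
#'
#' Dataset \eqn{k} has one row per retained match row; its \eqn{M} predictor
#' columns hold coordinate \eqn{k} of each slot detection (roster order) and
#' its target is coordinate \eqn{k} of the ground-truth box.  The four
#' datasets are row-aligned by construction.
#'
#' @param mt an imputed \code{matchTable} (see [imputeAndFilter()]).
#' @return named list over \code{x_min, y_min, x_max, y_max}; each element a
#'   list with matrix \code{X} (n x M) and numeric \code{y}.
#' @export
buildCoordinateDatasets <- function(mt) {
  stopifnot(inherits(mt, "matchTable"), !is.null(mt$fillFlags))
  if (nrow(mt$gt) == 0L)
    stop("no match rows available to build training datasets")
  detBox <- .boxMatrix(mt$dets)
  lapply(setNames(nm = .BOX_COLS), function(coord) {
    X <- matrix(detBox[mt$detIdx, coord], nrow = nrow(mt$detIdx),
                dimnames = list(NULL, mt$roster))
    list(X = X, y = mt$gt[[coord]])
  })
}

## ---- regressor backends -------------------------------------------------
## Each backend is a list(fit(X, y, seed) -> object, predict(object, X)).
## Ordinary least squares is the reference meta-learner; the tree ensembles
## are seeded so fits are reproducible.

.regressorBackends <- list(
  lr = list(
    fit = function(X, y, seed) {
      qrX <- qr(cbind(1, X))
      list(coef = qr.coef(qrX, y))
    },
    predict = function(object, X) {
      beta <- object$coef
      beta[is.na(beta)] <- 0
      drop(cbind(1, X) %*% beta)
    }),
  rf = list(
    fit = function(X, y, seed) {
      set.seed(seed)
      randomForest::randomForest(x = X, y = y, ntree = 200)
    },
    predict = function(object, X) unname(predict(object, X))),
  gb = list(
    fit = function(X, y, seed) {
      set.seed(seed)
      xgboost::xgboost(X, y, nrounds = 150, max_depth = 3,
                       learning_rate = 0.1, nthread = 1, verbosity = 0)
    },
    predict = function(object, X) predict(object, X)),
  xgb = list(
    fit = function(X, y, seed) {
      set.seed(seed)
      xgboost::xgboost(X, y, nrounds = 100, max_depth = 6,
                       learning_rate = 0.3, nthread = 1, verbosity = 0)
    },
    predict = function(object, X) predict(object, X))
)

#' Available meta-regressor backends
#' @return character vector of backend names usable in [stackBoxFit()].
#' @export
regressorBackends <- function() names(.regressorBackends)

#' Fit the stacking ensemble
#'
#' Runs the full training pipeline: match each base learner's detections to
#' the ground truths ([matchToGroundTruth()]), drop ground truths with no
#' match and fill missing slots from the row's best match
#' ([imputeAndFilter()]), build one regression dataset per box coordinate
#' ([buildCoordinateDatasets()]) and fit the chosen meta-regressor to each.
#'
#' @inheritParams matchToGroundTruth
#' @param regressor backend name; one of [regressorBackends()].  \code{"lr"}
#'   (ordinary least squares, the default) is deterministic and the variant
#'   with the best headline performance.
#' @param seed integer seed forwarded to stochastic backends.
#' @return a [StackBoxModel-class].
#' @examples
#' gt <- groundTruthTable("im1", c(10, 200), c(10, 200), c(80, 300), c(90, 310))
#' dets <- do.call(rbind, lapply(c("a", "b"), function(m)
#'   detectionTable(gt$image_id, gt$x_min + 3, gt$y_min, gt$x_max + 3,
#'                  gt$y_max, score = 0.9, model_id = m)))
#' fit <- stackBoxFit(gt, dets, seed = 1)
#' roster(fit)
#' @export
stackBoxFit <- function(gts, dets, roster = NULL, regressor = "lr",
                        minIou = 0, seed = 1L, exclusive = FALSE) {
  if (is.null(roster)) roster <- unique(dets$model_id)
  if (length(roster) < 2L)
    stop("stacking needs at least two base learners; got ", length(roster))
  if (!regressor %in% names(.regressorBackends))
    stop("unknown regressor backend '", regressor, "'; available: ",
         paste(names(.regressorBackends), collapse = ", "))
  mt <- matchToGroundTruth(gts, dets, roster, minIou, exclusive)
  mt <- imputeAndFilter(mt)
  ds <- buildCoordinateDatasets(mt)
  backend <- .regressorBackends[[regressor]]
  models <- lapply(ds, function(d) backend$fit(d$X, d$y, seed))
  new("StackBoxModel", roster = roster, regressorKind = regressor,
      models = models,
      trainInfo = list(nRows = nrow(mt$gt),
                       fillCounts = colSums(mt$fillFlags),
                       droppedGts = nrow(gts) - nrow(mt$gt),
                       minIou = minIou, seed = as.integer(seed)))
}
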