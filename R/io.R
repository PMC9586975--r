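#' @include AllClasses.R
NULL

#' Read COCO-format annotations
#'
#' Parses a COCO annotation JSON (\code{images}, \code{annotations} with
#' \code{bbox = [x, y, w, h]}, \code{categories}) into the package's
#' ground-truth table.  Boxes are converted to corner form by
#' \code{x_max = x + w}, \code{y_max = y + h}; zero-area annotations are
#' dropped with a message giving the count.
#'
#' @param path JSON file path.
#' @return list with \code{gts} and \code{images} data frames.
#' @export
readCocoAnnotations <- function(path) {
  j <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  for (key in c("images", "annotations"))
    if (is.null(j[[key]]))
      stop("COCO annotation file lacks the '", key, "' field: ", path)
  images <- data.frame(image_id = as.character(j$images$id),
                       width = j$images$width, height = j$images$height)
  ann <- j$annotations
  if (length(ann) == 0L || NROW(ann) == 0L)
    return(list(gts = groundTruthTable(character(0), numeric(0), numeric(0),
                                       numeric(0), numeric(0), integer(0)),
                images = images))
  if (is.null(ann$bbox) || is.null(ann$image_id))
    stop("annotation records need 'bbox' and 'image_id': ", path)
  bb <- do.call(rbind, ann$bbox)
  zero <- bb[, 3L] <= 0 | bb[, 4L] <= 0
  if (any(zero))
    message(sum(zero), " zero-area annotation(s) dropped")
  keep <- !zero
  gts <- groundTruthTable(as.character(ann$image_id[keep]),
                          bb[keep, 1L], bb[keep, 2L],
                          bb[keep, 1L] + bb[keep, 3L],
                          bb[keep, 2L] + bb[keep, 4L],
                          class_id = if (is.null(ann$category_id)) 1L
                                     else as.integer(ann$category_id[keep]))
  list(gts = gts, images = images)
}

#' Write COCO-format annotations
#'
#' @param gts ground-truth table.
#' @param images image table (\code{image_id}, \code{width}, \code{height}).
#' @param path output JSON path.
#' @export
writeCocoAnnotations <- function(gts, images, path) {
  .assertGroundTruth(gts)
  j <- list(
    images = data.frame(id = images$image_id, width = images$width,
                        height = images$height),
    annotations = list(),
    categories = data.frame(id = sort(unique(c(1L, gts$class_id))),
                            name = "object"))
  if (nrow(gts))
    j$annotations <- data.frame(
      id = seq_len(nrow(gts)), image_id = gts$image_id,
      category_id = gts$class_id,
      bbox = I(lapply(seq_len(nrow(gts)), function(i)
        c(gts$x_min[i], gts$y_min[i],
          gts$x_max[i] - gts$x_min[i], gts$y_max[i] - gts$y_min[i]))),
      area = boxArea(gts), iscrowd = 0L)
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Read COCO-format detection results
#'
#' Parses a COCO results JSON (records with \code{image_id},
#' \code{category_id}, \code{bbox = [x, y, w, h]}, \code{score}) and tags
#' every detection with \code{modelId}.  Scores outside \[0, 1\] raise an
#' error.
#'
#' @param path JSON file path.
#' @param modelId base-learner identifier to stamp on the detections.
#' @return a detection table.
#' @export
readCocoDetections <- function(path, modelId) {
  j <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (NROW(j) == 0L)
    return(detectionTable(character(0), numeric(0), numeric(0), numeric(0),
                          numeric(0), numeric(0), character(0), integer(0)))
  if (is.null(j$bbox) || is.null(j$score) || is.null(j$image_id))
    stop("detection records need 'image_id', 'bbox' and 'score': ", path)
  bb <- do.call(rbind, j$bbox)
  zero <- bb[, 3L] <= 0 | bb[, 4L] <= 0
  if (any(zero)) message(sum(zero), " zero-area detection(s) dropped")
  keep <- !zero
  detectionTable(as.character(j$image_id[keep]),
                 bb[keep, 1L], bb[keep, 2L],
                 bb[keep, 1L] + bb[keep, 3L], bb[keep, 2L] + bb[keep, 4L],
                 score = j$score[keep], model_id = modelId,
                 class_id = if (is.null(j$category_id)) 1L
                            else as.integer(j$category_id[keep]))
}

#' Write COCO-format detection results
#'
#' @param dets detection table.
#' @param path output JSON path.
#' @export
writeCocoDetections <- function(dets, path) {
  .assertDetections(dets)
  recs <- data.frame(
    image_id = dets$image_id, category_id = dets$class_id,
    bbox = I(lapply(seq_len(nrow(dets)), function(i)
      c(dets$x_min[i], dets$y_min[i],
        dets$x_max[i] - dets$x_min[i], dets$y_max[i] - dets$y_min[i]))),
    score = dets$score)
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Read/write the flat CSV detection dialect
#'
#' A convenience fixture format: columns \code{image_id}, \code{class_id},
#' \code{score}, \code{x_min}, \code{y_min}, \code{x_max}, \code{y_max},
#' \code{model_id} (corner coordinates, no conversion).
#'
#' @param path CSV file path.
#' @return \code{readDetectionsCsv}: a detection table.
#' @export
readDetectionsCsv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  detectionTable(df$image_id, df$x_min, df$y_min, df$x_max, df$y_max,
                 score = df$score, model_id = df$model_id,
                 class_id = df$class_id)
}

#' @rdname readDetectionsCsv
#' @param dets detection table.
#' @export
writeDetectionsCsv <- function(dets, path) {
  .assertDetections(dets)
  utils::write.csv(dets[.DET_COLS], path, row.names = FALSE)
  invisible(path)
}

## ---- model persistence --------------------------------------------------

#' Save and load fitted stacking models
#'
#' Least-squares models are stored transparently as their coefficient
#' vectors in versioned JSON; tree-ensemble backends are stored as a
#' base64-encoded serialized blob in the same envelope.
#'
#' @param model a [StackBoxModel-class].
#' @param path JSON file path.
#' @return \code{loadStackBoxModel}: the restored model.
#' @export
saveStackBoxModel <- function(model, path) {
  stopifnot(is(model, "StackBoxModel"))
  payload <- if (model@regressorKind == "lr")
    lapply(model@models, function(m) unname(m$coef))
  else
    lapply(model@models, function(m) jsonlite::base64_enc(serialize(m, NULL)))
  j <- list(format = "stackbox-model", version = 1L,
            roster = model@roster, regressorKind = model@regressorKind,
            encoding = if (model@regressorKind == "lr") "coefficients"
                       else "serialized-blob",
            models = payload, trainInfo = model@trainInfo)
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname saveStackBoxModel
#' @export
loadStackBoxModel <- function(path) {
  j <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!identical(j$format, "stackbox-model"))
    stop("not a stackbox model file: ", path)
  models <- if (identical(j$encoding, "coefficients"))
    lapply(j$models, function(b) list(coef = as.numeric(b)))
  else
    lapply(j$models, function(b) unserialize(jsonlite::base64_dec(b)))
  ti <- as.list(j$trainInfo)
  if (!is.null(ti$fillCounts)) ti$fillCounts <- unlist(ti$fillCounts)
  new("StackBoxModel", roster = j$roster, regressorKind = j$regressorKind,
      models = models[.BOX_COLS], trainInfo = ti)
}

## ---- run configuration --------------------------------------------------

#' Read and write run configurations
#'
#' A run configuration is a named list (roster, file paths, fusion and
#' stacking parameters, regressor kind, seed, fold count, coordinate
#' dialect flags, log level) serialized to YAML; the round trip is
#' lossless for scalars, vectors and nested lists.
#'
#' @param config named list.
#' @param path YAML file path.
#' @return \code{readRunConfig}: the configuration list.
#' @export
writeRunConfig <- function(config, path) {
  stopifnot(is.list(config))
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) yaml::read_yaml(path)

#' Default run configuration
#' @return named list of defaults accepted by [runCrossval()].
#' @export
defaultRunConfig <- function() {
  list(regressor = "lr", nFolds = 5L, seed = 1L, minIou = 0,
       iouThreshold = 0.5, confMode = "mean",
       coordinateDialect = "corners", logLevel = "info")
}

## ---- cross-validation harness -------------------------------------------

#' Assign images to disjoint folds
#'
#' @param imageIds character vector (duplicates allowed; assignment is per
#'   unique image).
#' @param nFolds number of folds.
#' @param seed shuffling seed.
#' @return named integer vector: fold number per unique image id.
#' @export
assignFolds <- function(imageIds, nFolds = 5L, seed = 1L) {
  ids <- unique(imageIds)
  if (length(ids) < nFolds)
    stop("fewer images (", length(ids), ") than folds (", nFolds, ")")
  set.seed(seed)
  shuffled <- sample(ids)
  folds <- rep(seq_len(nFolds), length.out = length(ids))
  setNames(folds[match(ids, shuffled)], ids)
}

#' Cross-validated comparison of base learners, fusion baselines and StackBox
#'
#' Splits the images into \code{nFolds} disjoint folds.  For each fold the
#' stacking model is fitted on the training images and applied to the
#' held-out images; each base learner and each requested fusion baseline is
#' evaluated on the same held-out detections.  Per-fold metric reports are
#' summarised as mean ± sample SD.
#'
#' @param gts ground-truth table.
#' @param dets pooled detection table over all base learners.
#' @param roster ordered base-learner identifiers.
#' @param nFolds fold count (default 5).
#' @param regressor meta-regressor backend (default \code{"lr"}).
#' @param seed seed for fold assignment and stochastic backends.
#' @param fusionMethods fusion baselines to evaluate alongside.
#' @param minIou availability cutoff for stacking match rows.
#' @return list: \code{folds} (per-algorithm lists of per-fold
#'   [MetricsReport-class]s), \code{summaries} (per-algorithm
#'   [crossvalSummary()] frames), \code{table} (markdown lines) and
#'   \code{foldAssignment}.
#' @export
runCrossval <- function(gts, dets, roster = NULL, nFolds = 5L,
                        regressor = "lr", seed = 1L,
                        fusionMethods = c("nms", "wbf"), minIou = 0) {
  .assertGroundTruth(gts); .assertDetections(dets)
  if (is.null(roster)) roster <- unique(dets$model_id)
  folds <- assignFolds(gts$image_id, nFolds, seed)
  algos <- c(roster, fusionMethods, "stackbox")
  perFold <- lapply(seq_len(nFolds), function(k) {
    testImgs <- names(folds)[folds == k]
    gtTrain <- gts[!gts$image_id %in% testImgs, , drop = FALSE]
    gtTest <- gts[gts$image_id %in% testImgs, , drop = FALSE]
    detTrain <- dets[!dets$image_id %in% testImgs, , drop = FALSE]
    detTest <- dets[dets$image_id %in% testImgs, , drop = FALSE]
    fit <- stackBoxFit(gtTrain, detTrain, roster, regressor,
                       minIou = minIou, seed = seed)
    stacked <- stackBoxPredict(fit, detTest, minIou = minIou)
    reports <- c(
      lapply(setNames(nm = roster), function(m)
        evaluateDetections(gtTest,
                           detTest[detTest$model_id == m, , drop = FALSE])),
      lapply(setNames(nm = fusionMethods), function(f)
        evaluateDetections(gtTest, fuseDetections(detTest, f,
                                                  roster = roster))),
      list(stackbox = evaluateDetections(gtTest, stacked)))
    reports
  })
  byAlgo <- lapply(setNames(nm = algos), function(a)
    lapply(perFold, `[[`, a))
  summaries <- lapply(byAlgo, crossvalSummary)
  list(folds = byAlgo, summaries = summaries,
       table = formatMetricsTable(summaries),
       foldAssignment = folds)
}
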