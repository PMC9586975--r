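#' @include geometry.R tables.R
NULL

#' Fusion configuration
#'
#' Holds the tunable parameters shared by the box-fusion baselines.
#'
#' @slot iouThreshold IoU overlap above which boxes are considered redundant
#'   (suppressed, rescored or clustered, depending on the method); default 0.5.
#' @slot softSigma Gaussian decay scale of Soft-NMS; default 0.5.
#' @slot softScoreThreshold minimum score a Soft-NMS survivor may keep;
#'   default 0.001.
#' @slot confMode how WBF assigns the fused confidence: \code{"average"}
#'   (default) or \code{"maximum"} (the WBF-max variant).
#' @slot modelWeights named non-negative per-model weights for WBF; empty
#'   means all 1.
#' @slot wbfRescale logical; rescale the fused WBF confidence by the fraction
#'   of models contributing to the cluster (default \code{TRUE}).
#' @export
setClass("FusionConfig",
  representation(iouThreshold = "numeric", softSigma = "numeric",
                 softScoreThreshold = "numeric", confMode = "character",
                 modelWeights = "numeric", wbfRescale = "logical"),
  prototype(iouThreshold = 0.5, softSigma = 0.5, softScoreThreshold = 0.001,
            confMode = "average", modelWeights = numeric(0), wbfRescale = TRUE),
  validity = function(object) {
    msg <- character(0)
    if (object@iouThreshold <= 0 || object@iouThreshold > 1)
      msg <- c(msg, "iouThreshold must lie in (0, 1]")
    if (object@softSigma <= 0) msg <- c(msg, "softSigma must be > 0")
    if (object@softScoreThreshold < 0 || object@softScoreThreshold > 1)
      msg <- c(msg, "softScoreThreshold must lie in [0, 1]")
    if (!object@confMode %in% c("average", "maximum"))
      msg <- c(msg, "confMode must be 'average' or 'maximum'")
    if (length(object@modelWeights) && any(object@modelWeights < 0))
      msg <- c(msg, "modelWeights must be non-negative")
    if (length(msg)) msg else TRUE
  })

#' @rdname FusionConfig-class
#' @param iouThreshold,softSigma,softScoreThreshold,confMode,modelWeights,wbfRescale
#'   see the corresponding slots.
#' @return a \code{FusionConfig} object.
#' @export
fusionConfig <- function(iouThreshold = 0.5, softSigma = 0.5,
                         softScoreThreshold = 0.001,
                         confMode = c("average", "maximum"),
                         modelWeights = numeric(0), wbfRescale = TRUE) {
  new("FusionConfig", iouThreshold = iouThreshold, softSigma = softSigma,
      softScoreThreshold = softScoreThreshold,
      confMode = match.arg(confMode),
      modelWeights = modelWeights, wbfRescale = wbfRescale)
}

#' @export
setMethod("show", "FusionConfig", function(object) {
  cat("FusionConfig: iouThreshold=", object@iouThreshold,
      ", softSigma=", object@softSigma,
      ", softScoreThreshold=", object@softScoreThreshold,
      ", confMode=", object@confMode,
      ", wbfRescale=", object@wbfRescale, "\n", sep = "")
})

#' Fitted stacking ensemble
#'
#' A \code{StackBoxModel} holds one fitted meta-regressor per box coordinate
#' (\code{x_min}, \code{y_min}, \code{x_max}, \code{y_max}) together with the
#' ordered roster of base learners whose predictions form the regressors'
#' design matrix.  Create it with [stackBoxFit()]; apply it with
#' [stackBoxPredict()].
#'
#' @slot roster ordered character vector of base-learner identifiers; its
#'   order fixes the predictor-column order of all four regressors.
#' @slot regressorKind backend name (\code{"lr"}, \code{"rf"}, \code{"gb"}
#'   or \code{"xgb"}).
#' @slot models named list of four fitted backend objects, one per
#'   coordinate.
#' @slot trainInfo list of training metadata: retained row count, fill
#'   (imputation) counts per model, the minimum-IoU availability cutoff and
#'   the seed.
#' @export
setClass("StackBoxModel",
  representation(roster = "character", regressorKind = "character",
                 models = "list", trainInfo = "list"),
  validity = function(object) {
    msg <- character(0)
    if (length(object@roster) < 2L)
      msg <- c(msg, "roster must contain at least two base learners")
    if (anyDuplicated(object@roster))
      msg <- c(msg, "roster identifiers must be unique")
    if (!identical(sort(names(object@models)), sort(.BOX_COLS)))
      msg <- c(msg, "models must be a named list with one entry per coordinate")
    if (length(msg)) msg else TRUE
  })

#' @describeIn StackBoxModel-class ordered base-learner identifiers.
#' @param object,x a \code{StackBoxModel}.
#' @export
setGeneric("roster", function(x) standardGeneric("roster"))

#' @rdname StackBoxModel-class
#' @export
setMethod("roster", "StackBoxModel", function(x) x@roster)

#' @describeIn StackBoxModel-class meta-regressor backend name.
#' @export
setGeneric("regressorKind", function(x) standardGeneric("regressorKind"))

#' @rdname StackBoxModel-class
#' @export
setMethod("regressorKind", "StackBoxModel", function(x) x@regressorKind)

#' @export
setMethod("show", "StackBoxModel", function(object) {
  cat("StackBoxModel (", object@regressorKind, " meta-regressors)\n", sep = "")
  cat("  roster (", length(object@roster), " base learners): ",
      paste(object@roster, collapse = ", "), "\n", sep = "")
  ti <- object@trainInfo
  if (!is.null(ti$nRows))
    cat("  trained on ", ti$nRows, " match rows; imputed slots: ",
        paste(sprintf("%s=%d", names(ti$fillCounts), ti$fillCounts),
              collapse = ", "), "\n", sep = "")
})

#' Per-model noise profile of the synthetic simulator
#'
#' Describes how one simulated base learner corrupts the ground truth: each
#' coordinate \eqn{c} of a detected box is emitted as
#' \eqn{a_k c + b_k + N(0, \sigma^2)} and clipped to the image; whole boxes
#' are missed with probability \code{missRate}; spurious boxes arrive as a
#' Poisson stream of \code{fpRate} per image.  Confidences are Beta-drawn,
#' with a higher mean for true detections than for false positives.
#'
#' @slot scale,offset length-4 numeric affine parameters \eqn{a_k},
#'   \eqn{b_k}, ordered \code{x_min, y_min, x_max, y_max}.
#' @slot jitterSd Gaussian coordinate noise, pixels.
#' @slot missRate probability of dropping a ground truth.
#' @slot fpRate expected false positives per image.
#' @slot confTp,confFp length-2 Beta shape parameters of the true-positive
#'   and false-positive confidence distributions.
#' @export
setClass("NoiseProfile",
  representation(scale = "numeric", offset = "numeric", jitterSd = "numeric",
                 missRate = "numeric", fpRate = "numeric",
                 confTp = "numeric", confFp = "numeric"),
  prototype(scale = rep(1, 4), offset = rep(0, 4), jitterSd = 0,
            missRate = 0, fpRate = 0, confTp = c(8, 2), confFp = c(2, 6)),
  validity = function(object) {
    msg <- character(0)
    if (length(object@scale) != 4L || length(object@offset) != 4L)
      msg <- c(msg, "scale and offset must have length 4")
    if (object@jitterSd < 0) msg <- c(msg, "jitterSd must be >= 0")
    if (object@missRate < 0 || object@missRate > 1)
      msg <- c(msg, "missRate must lie in [0, 1]")
    if (object@fpRate < 0) msg <- c(msg, "fpRate must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' @rdname NoiseProfile-class
#' @param scale,offset,jitterSd,missRate,fpRate,confTp,confFp see slots.
#' @return a \code{NoiseProfile} object.
#' @export
noiseProfile <- function(scale = rep(1, 4), offset = rep(0, 4), jitterSd = 0,
                         missRate = 0, fpRate = 0,
                         confTp = c(8, 2), confFp = c(2, 6)) {
  if (length(scale) == 1L) scale <- rep(scale, 4)
  if (length(offset) == 1L) offset <- rep(offset, 4)
  new("NoiseProfile", scale = as.numeric(scale), offset = as.numeric(offset),
      jitterSd = jitterSd, missRate = missRate, fpRate = fpRate,
      confTp = confTp, confFp = confFp)
}

#' @export
setMethod("show", "NoiseProfile", function(object) {
  cat("NoiseProfile: scale=(", paste(object@scale, collapse = ", "),
      "), offset=(", paste(object@offset, collapse = ", "),
      "), jitterSd=", object@jitterSd, ", missRate=", object@missRate,
      ", fpRate=", object@fpRate, "\n", sep = "")
})

#' Synthetic detection scenario
#'
#' A seeded description of a simulated dataset: images of a fixed size, a
#' uniform count of ground-truth boxes per image with log-uniform areas
#' spanning the medium and large COCO buckets, and one [NoiseProfile-class]
#' per simulated base learner.  Realise it with [simulateScenario()].
#'
#' @slot nImages number of images.
#' @slot imageWidth,imageHeight image size in pixels.
#' @slot boxesPerImage length-2 integer range (uniform, inclusive).
#' @slot areaRange length-2 numeric range of box areas (log-uniform), px^2.
#' @slot aspectRange length-2 numeric range of width/height aspect ratios.
#' @slot profiles named list of \code{NoiseProfile}s, one per base learner;
#'   names form the model roster.
#' @slot seed integer base seed; all sampling derives from it.
#' @export
setClass("SyntheticScenario",
  representation(nImages = "integer", imageWidth = "numeric",
                 imageHeight = "numeric", boxesPerImage = "integer",
                 areaRange = "numeric", aspectRange = "numeric",
                 profiles = "list", seed = "integer"),
  validity = function(object) {
    msg <- character(0)
    if (object@nImages < 0L) msg <- c(msg, "nImages must be >= 0")
    if (object@imageWidth <= 0 || object@imageHeight <= 0)
      msg <- c(msg, "image dimensions must be positive")
    if (length(object@boxesPerImage) != 2L ||
        any(object@boxesPerImage < 1L) ||
        object@boxesPerImage[1] > object@boxesPerImage[2])
      msg <- c(msg, "boxesPerImage must be an increasing positive pair")
    if (object@areaRange[1] <= 0 || object@areaRange[1] > object@areaRange[2])
      msg <- c(msg, "areaRange must be positive and increasing")
    if (sqrt(object@areaRange[2]) > min(object@imageWidth, object@imageHeight))
      msg <- c(msg, "largest box does not fit inside the image")
    if (length(object@profiles) == 0L || is.null(names(object@profiles)) ||
        anyDuplicated(names(object@profiles)))
      msg <- c(msg, "profiles must be a uniquely named list")
    if (!all(vapply(object@profiles, is, TRUE, "NoiseProfile")))
      msg <- c(msg, "profiles must all be NoiseProfile objects")
    if (length(msg)) msg else TRUE
  })

#' @rdname SyntheticScenario-class
#' @param nImages,imageWidth,imageHeight,boxesPerImage,areaRange,aspectRange,profiles,seed
#'   see slots.
#' @return a \code{SyntheticScenario} object.
#' @export
syntheticScenario <- function(nImages, profiles, seed = 1L,
                              imageWidth = 640, imageHeight = 640,
                              boxesPerImage = c(1L, 3L),
                              areaRange = c(40^2, 200^2),
                              aspectRange = c(0.6, 1.6)) {
  new("SyntheticScenario", nImages = as.integer(nImages),
      imageWidth = imageWidth, imageHeight = imageHeight,
      boxesPerImage = as.integer(boxesPerImage),
      areaRange = as.numeric(areaRange), aspectRange = as.numeric(aspectRange),
      profiles = profiles, seed = as.integer(seed))
}

#' @export
setMethod("show", "SyntheticScenario", function(object) {
  cat("SyntheticScenario: ", object@nImages, " images of ",
      object@imageWidth, "x", object@imageHeight, " px, ",
      object@boxesPerImage[1], "-", object@boxesPerImage[2],
      " boxes/image, seed ", object@seed, "\n", sep = "")
  cat("  base learners: ", paste(names(object@profiles), collapse = ", "),
      "\n", sep = "")
})

#' Detection metrics report
#'
#' The ten-headline evaluation of a detection set against ground truths:
#' AP over the IoU grid .5:.05:.95, AP at IoU .50 and .75, medium/large
#' size-bucketed AP, average recall at 1 and 10 detections per image,
#' size-bucketed AR, and class-averaged mAP at IoU .50.  Values are in
#' \[0, 1\]; a bucket with no ground truths yields \code{NA}.
#'
#' @slot values named numeric vector of the ten metrics.
#' @slot nGroundTruth,nDetections counts the report was computed from.
#' @export
setClass("MetricsReport",
  representation(values = "numeric", nGroundTruth = "integer",
                 nDetections = "integer"),
  validity = function(object) {
    need <- .METRIC_NAMES
    if (!identical(names(object@values), need))
      return(paste("values must be named:", paste(need, collapse = ", ")))
    v <- object@values[!is.na(object@values)]
    if (any(v < 0 | v > 1)) return("metric values must lie in [0, 1]")
    TRUE
  })

.METRIC_NAMES <- c("ap_range", "ap_50", "ap_75", "ap_medium", "ap_large",
                   "ar_1", "ar_10", "ar_medium", "ar_large", "map_50")

#' @describeIn MetricsReport-class named numeric vector of the ten metrics.
#' @param x,object a \code{MetricsReport}.
#' @export
setGeneric("metricValues", function(x) standardGeneric("metricValues"))

#' @rdname MetricsReport-class
#' @export
setMethod("metricValues", "MetricsReport", function(x) x@values)

#' @export
setMethod("show", "MetricsReport", function(object) {
  cat("MetricsReport (", object@nGroundTruth, " ground truths, ",
      object@nDetections, " detections)\n", sep = "")
  v <- object@values
  print(round(v, 4))
})
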