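#' @include AllClasses.R
NULL

# Named substreams derived from the scenario seed so that adding a model, or
# changing one model's profile, never perturbs ground-truth sampling or the
# draws of the other models.  Offsets stay well below 2^31.
.subSeed <- function(seed, stream, index = 0L) {
  (as.integer(seed) + 101L * index +
     sum(utf8ToInt(stream)) * 7919L) %% .Machine$integer.max
}

#' Generate ground-truth boxes for a synthetic scenario
#'
#' Samples, under the scenario's seed, a uniform number of boxes per image;
#' each box has a log-uniform area (spanning the medium and large COCO
#' buckets under the default range), a uniform aspect ratio, and a uniform
#' position subject to fitting inside the image.
#'
#' @param scenario a [SyntheticScenario-class].
#' @return list with \code{gts} (ground-truth table) and \code{images}
#'   (data frame of \code{image_id}, \code{width}, \code{height}).
#' @export
generateGroundTruth <- function(scenario) {
  stopifnot(is(scenario, "SyntheticScenario"))
  n <- scenario@nImages
  images <- data.frame(image_id = sprintf("img%04d", seq_len(n)),
                       width = rep(scenario@imageWidth, n),
                       height = rep(scenario@imageHeight, n))
  if (n == 0L)
    return(list(gts = groundTruthTable(character(0), numeric(0), numeric(0),
                                       numeric(0), numeric(0), integer(0)),
                images = images))
  set.seed(.subSeed(scenario@seed, "gt"))
  span <- scenario@boxesPerImage[2] - scenario@boxesPerImage[1] + 1L
  counts <- scenario@boxesPerImage[1] + sample.int(span, n, replace = TRUE) - 1L
  total <- sum(counts)
  area <- exp(runif(total, log(scenario@areaRange[1]),
                    log(scenario@areaRange[2])))
  aspect <- runif(total, scenario@aspectRange[1], scenario@aspectRange[2])
  w <- pmin(sqrt(area * aspect), scenario@imageWidth - 1e-6)
  h <- pmin(area / w, scenario@imageHeight - 1e-6)
  x0 <- runif(total, 0, scenario@imageWidth - w)
  y0 <- runif(total, 0, scenario@imageHeight - h)
  gts <- groundTruthTable(rep(images$image_id, counts),
                          x0, y0, x0 + w, y0 + h)
  list(gts = gts, images = images)
}

#' Simulate one base learner's detections
#'
#' Applies a [NoiseProfile-class] to the ground truths: each box is missed
#' independently with \code{missRate}; surviving boxes are emitted with
#' coordinates \eqn{a_k c_k + b_k + N(0, \sigma^2)} clipped to the image;
#' \code{Poisson(fpRate)} false positives per image are placed uniformly
#' with the same size distribution as the ground truths.  True and false
#' detections draw Beta confidences from \code{confTp} and \code{confFp}.
#'
#' @param gts ground-truth table.
#' @param images image table from [generateGroundTruth()].
#' @param profile a [NoiseProfile-class].
#' @param modelId identifier stamped on the produced detections.
#' @param seed integer seed for this model's stream.
#' @param areaRange,aspectRange size distribution used for false positives.
#' @return a detection table.
#' @export
simulateBaseLearner <- function(gts, images, profile, modelId, seed,
                                areaRange = c(40^2, 200^2),
                                aspectRange = c(0.6, 1.6)) {
  stopifnot(is(profile, "NoiseProfile"))
  .assertGroundTruth(gts)
  set.seed(seed)
  width <- images$width[1L]; height <- images$height[1L]
  n <- nrow(gts)
  keep <- if (n) runif(n) >= profile@missRate else logical(0)
  tp <- gts[keep, , drop = FALSE]
  if (nrow(tp)) {
    m <- .boxMatrix(tp)
    m <- sweep(sweep(m, 2L, profile@scale, `*`), 2L, profile@offset, `+`)
    if (profile@jitterSd > 0)
      m <- m + matrix(rnorm(length(m), 0, profile@jitterSd), nrow(m))
    tp[.BOX_COLS] <- as.data.frame(m)
    tp$score <- rbeta(nrow(tp), profile@confTp[1], profile@confTp[2])
    tp$model_id <- modelId
    tp <- suppressMessages(clipBoxes(tp, width, height, "clip"))
  } else {
    tp <- detectionTable(character(0), numeric(0), numeric(0), numeric(0),
                         numeric(0), numeric(0), character(0), integer(0))
  }
  nFp <- rpois(nrow(images), profile@fpRate)
  totalFp <- sum(nFp)
  if (totalFp > 0L) {
    area <- exp(runif(totalFp, log(areaRange[1]), log(areaRange[2])))
    aspect <- runif(totalFp, aspectRange[1], aspectRange[2])
    w <- pmin(sqrt(area * aspect), width - 1e-6)
    h <- pmin(area / w, height - 1e-6)
    x0 <- runif(totalFp, 0, width - w)
    y0 <- runif(totalFp, 0, height - h)
    fp <- detectionTable(rep(images$image_id, nFp), x0, y0, x0 + w, y0 + h,
                         score = rbeta(totalFp, profile@confFp[1],
                                       profile@confFp[2]),
                         model_id = modelId)
    tp <- rbind(tp, fp)
  }
  rownames(tp) <- NULL
  tp
}

#' Realise a synthetic scenario
#'
#' Generates the ground truths and one detection set per configured base
#' learner, each from its own seed substream.
#'
#' @param scenario a [SyntheticScenario-class].
#' @return list with \code{gts}, \code{images}, \code{dets} (all models
#'   pooled, tagged by \code{model_id}) and \code{roster}.
#' @export
simulateScenario <- function(scenario) {
  gt <- generateGroundTruth(scenario)
  roster <- names(scenario@profiles)
  dets <- do.call(rbind, lapply(seq_along(roster), function(i)
    simulateBaseLearner(gt$gts, gt$images, scenario@profiles[[i]],
                        roster[i],
                        seed = .subSeed(scenario@seed, "model", i),
                        areaRange = scenario@areaRange,
                        aspectRange = scenario@aspectRange)))
  rownames(dets) <- NULL
  list(gts = gt$gts, images = gt$images, dets = dets, roster = roster)
}

#' Packaged synthetic scenarios
#'
#' Three named presets exercise the stacking pipeline under increasingly
#' hostile conditions, each with three simulated base learners:
#' \describe{
#'   \item{perfect}{zero noise — every learner reproduces the ground truth
#'     exactly (confidences still random); 200 images by default.}
#'   \item{bias}{each learner applies a distinct systematic affine
#'     distortion (a diagonal shift, a dilation, and a compressive
#'     rescaling), plus 2 px Gaussian jitter, a 10\% miss rate and 0.5
#'     false positives per image; 500 images by default.}
#'   \item{hard}{the same biases with 6 px jitter, a 25\% miss rate and 1
#'     false positive per image.}
#' }
#'
#' @param name preset name.
#' @param nImages number of images; default depends on the preset.
#' @param seed scenario seed.
#' @return a [SyntheticScenario-class].
#' @examples
#' sc <- presetScenario("bias", seed = 7)
#' names(sc@profiles)
#' @export
presetScenario <- function(name = c("perfect", "bias", "hard"),
                           nImages = NULL, seed = 1L) {
  name <- match.arg(name)
  # Distortions are calibrated so each simulated learner sits in the
  # operating regime typical of real single-stage polyp detectors: most
  # detections clear IoU .5 but almost none clear IoU .75.  The three
  # affine maps are distinct and do not cancel on average, so a
  # confidence-weighted box average stays biased while a least-squares
  # meta-regression can invert each map exactly.
  biasProfiles <- function(jitter, miss, fp) list(
    shiftNet = noiseProfile(scale = rep(1.02, 4), offset = rep(8, 4),
                            jitterSd = jitter, missRate = miss, fpRate = fp),
    stretchNet = noiseProfile(scale = c(1.04, 1, 1.04, 1),
                              offset = c(-5, 14, -5, 14), jitterSd = jitter,
                              missRate = miss, fpRate = fp),
    dilateNet = noiseProfile(scale = rep(1.01, 4),
                             offset = c(-12, -12, 12, 12), jitterSd = jitter,
                             missRate = miss, fpRate = fp))
  switch(name,
    perfect = syntheticScenario(
      nImages = if (is.null(nImages)) 200L else nImages,
      profiles = list(alpha = noiseProfile(), beta = noiseProfile(),
                      gamma = noiseProfile()),
      seed = seed),
    bias = syntheticScenario(
      nImages = if (is.null(nImages)) 500L else nImages,
      profiles = biasProfiles(2, 0.1, 0.5), seed = seed),
    hard = syntheticScenario(
      nImages = if (is.null(nImages)) 500L else nImages,
      profiles = biasProfiles(6, 0.25, 1), seed = seed))
}
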