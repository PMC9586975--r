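#' @include geometry.R
NULL

#' @name tables
#' @title Detection and ground-truth tables
#'
#' @description
#' Detections and ground truths travel through the package as plain data
#' frames with a fixed column contract, one row per box:
#' \itemize{
#'   \item ground truths: \code{image_id}, \code{class_id},
#'     \code{x_min}, \code{y_min}, \code{x_max}, \code{y_max};
#'   \item detections: the same columns plus \code{score} in \[0, 1\] and
#'     \code{model_id} naming the producing base learner.
#' }
#' The constructors below validate the contract (finite, positively sized
#' boxes; scores inside the unit interval) and are the recommended way to
#' build the tables by hand; the COCO readers and the simulator emit them
#' already validated.
NULL

.GT_COLS  <- c("image_id", "class_id", .BOX_COLS)
.DET_COLS <- c(.GT_COLS, "score", "model_id")

#' Build a validated ground-truth table
#'
#' @param image_id character or integer image identifiers (recycled).
#' @param x_min,y_min,x_max,y_max box corner coordinates in pixels.
#' @param class_id integer class labels (default 1, the single-class case).
#' @return a data frame with the ground-truth column contract.
#' @export
groundTruthTable <- function(image_id, x_min, y_min, x_max, y_max,
                             class_id = 1L) {
  df <- data.frame(image_id = as.character(image_id),
                   class_id = as.integer(class_id),
                   x_min = as.numeric(x_min), y_min = as.numeric(y_min),
                   x_max = as.numeric(x_max), y_max = as.numeric(y_max),
                   stringsAsFactors = FALSE)
  .assertValidBoxes(.boxMatrix(df), "ground-truth box")
  df
}

#' Build a validated detection table
#'
#' @inheritParams groundTruthTable
#' @param score confidence scores in \[0, 1\].
#' @param model_id identifier of the producing base learner (recycled).
#' @return a data frame with the detection column contract.
#' @export
detectionTable <- function(image_id, x_min, y_min, x_max, y_max, score,
                           model_id = "model", class_id = 1L) {
  df <- groundTruthTable(image_id, x_min, y_min, x_max, y_max, class_id)
  df$score <- as.numeric(score)
  df$model_id <- as.character(model_id)
  if (any(!is.finite(df$score)) || any(df$score < 0 | df$score > 1))
    stop("detection scores must lie in [0, 1]")
  df
}

.assertDetections <- function(dets) {
  missing <- setdiff(.DET_COLS, names(dets))
  if (length(missing))
    stop("detection table lacks column(s): ", paste(missing, collapse = ", "))
  if (nrow(dets) && (any(!is.finite(dets$score)) ||
                     any(dets$score < 0 | dets$score > 1)))
    stop("detection scores must lie in [0, 1]")
  invisible(TRUE)
}

.assertGroundTruth <- function(gts) {
  missing <- setdiff(.GT_COLS, names(gts))
  if (length(missing))
    stop("ground-truth table lacks column(s): ", paste(missing, collapse = ", "))
  invisible(TRUE)
}

#' Area buckets for size-stratified metrics
#'
#' Assigns each box to \code{"small"}, \code{"medium"} or \code{"large"}
#' following the COCO convention: medium means an area in
#' \code{[32^2, 96^2)} squared pixels and large means \code{>= 96^2};
#' anything below \code{32^2} is small.
#'
#' @param boxes box table or matrix.
#' @param thresholds length-2 numeric: lower edges of the medium and large
#'   buckets in squared pixels.
#' @return character vector of bucket names.
#' @export
areaBucket <- function(boxes, thresholds = c(32^2, 96^2)) {
  a <- boxArea(boxes)
  cut(a, breaks = c(-Inf, thresholds, Inf),
      labels = c("small", "medium", "large"), right = FALSE) |> as.character()
}
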