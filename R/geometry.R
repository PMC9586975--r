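#' @name geometry
#' @title Box geometry: areas, intersection over union, clipping
#'
#' @description
#' Boxes are axis-aligned rectangles in continuous pixel coordinates with the
#' origin at the top-left corner, stored as the four columns
#' \code{x_min}, \code{y_min}, \code{x_max}, \code{y_max} of a data frame (or
#' a 4-column matrix).  Width is \code{x_max - x_min} exactly: no half-open
#' pixel semantics are applied, so a box from 0 to 10 has side 10.
#' A box is valid when \code{x_min < x_max}, \code{y_min < y_max} and all
#' coordinates are finite.
NULL

.BOX_COLS <- c("x_min", "y_min", "x_max", "y_max")

# Coerce a data.frame/matrix/length-4 vector to an n x 4 coordinate matrix.
.boxMatrix <- function(b) {
  if (is.matrix(b)) {
    stopifnot(ncol(b) == 4L)
    m <- b
    colnames(m) <- .BOX_COLS
  } else if (is.data.frame(b)) {
    missing <- setdiff(.BOX_COLS, names(b))
    if (length(missing))
      stop("box table lacks column(s): ", paste(missing, collapse = ", "))
    m <- as.matrix(b[.BOX_COLS])
  } else if (is.numeric(b) && length(b) == 4L) {
    m <- matrix(b, nrow = 1L, dimnames = list(NULL, .BOX_COLS))
  } else {
    stop("cannot interpret object of class '", class(b)[1L], "' as boxes")
  }
  storage.mode(m) <- "double"
  m
}

.assertValidBoxes <- function(m, what = "box") {
  if (nrow(m) == 0L) return(invisible(TRUE))
  if (!all(is.finite(m)))
    stop(what, " coordinates must all be finite")
  bad <- m[, "x_min"] >= m[, "x_max"] | m[, "y_min"] >= m[, "y_max"]
  if (any(bad))
    stop(sum(bad), " invalid ", what, "(es): need x_min < x_max and y_min < y_max")
  invisible(TRUE)
}

#' Box areas
#'
#' @param boxes data frame or matrix with columns
#'   \code{x_min, y_min, x_max, y_max}, or a single length-4 numeric vector.
#' @return numeric vector of areas in squared pixels.
#' @examples
#' boxArea(c(0, 0, 10, 10))      # 100
#' boxArea(c(2, 3, 7, 11))       # 40
#' @export
boxArea <- function(boxes) {
  m <- .boxMatrix(boxes)
  .assertValidBoxes(m)
  unname((m[, "x_max"] - m[, "x_min"]) * (m[, "y_max"] - m[, "y_min"]))
}

#' Intersection over union of two boxes (or paired rows)
#'
#' @param a,b boxes as in [boxArea()]; if both have several rows they are
#'   compared row-wise and must have equal row counts.
#' @return numeric vector of IoU values in \[0, 1\]; 0 for disjoint pairs.
#' @examples
#' boxIoU(c(0, 0, 10, 10), c(5, 5, 15, 15))  # 25/175
#' @export
boxIoU <- function(a, b) {
  ma <- .boxMatrix(a); mb <- .boxMatrix(b)
  .assertValidBoxes(ma); .assertValidBoxes(mb)
  if (nrow(ma) != nrow(mb)) {
    if (nrow(ma) == 1L) ma <- ma[rep(1L, nrow(mb)), , drop = FALSE]
    else if (nrow(mb) == 1L) mb <- mb[rep(1L, nrow(ma)), , drop = FALSE]
    else stop("row counts differ")
  }
  iw <- pmin(ma[, "x_max"], mb[, "x_max"]) - pmax(ma[, "x_min"], mb[, "x_min"])
  ih <- pmin(ma[, "y_max"], mb[, "y_max"]) - pmax(ma[, "y_min"], mb[, "y_min"])
  inter <- pmax(iw, 0) * pmax(ih, 0)
  union <- boxArea(ma) + boxArea(mb) - inter
  unname(ifelse(union > 0, inter / union, 0))
}

#' All-pairs IoU matrix
#'
#' @param a,b box tables (see [boxArea()]).
#' @return an \code{nrow(a)} by \code{nrow(b)} matrix of IoU values.
#' @export
iouMatrix <- function(a, b) {
  ma <- .boxMatrix(a); mb <- .boxMatrix(b)
  .assertValidBoxes(ma); .assertValidBoxes(mb)
  n <- nrow(ma); m <- nrow(mb)
  if (n == 0L || m == 0L) return(matrix(0, n, m))
  ix1 <- outer(ma[, "x_min"], mb[, "x_min"], pmax)
  ix2 <- outer(ma[, "x_max"], mb[, "x_max"], pmin)
  iy1 <- outer(ma[, "y_min"], mb[, "y_min"], pmax)
  iy2 <- outer(ma[, "y_max"], mb[, "y_max"], pmin)
  inter <- pmax(ix2 - ix1, 0) * pmax(iy2 - iy1, 0)
  union <- outer(boxArea(ma), boxArea(mb), `+`) - inter
  out <- inter / union
  out[union <= 0] <- 0
  out
}

#' Clip boxes to image bounds or drop degenerate ones
#'
#' Under \code{policy = "clip"} coordinates are clamped into
#' \code{[0, width] x [0, height]}; boxes left with no positive extent on
#' either axis are removed (with a message giving the count).  Under
#' \code{policy = "drop"} any box not entirely valid inside the image after
#' clamping is removed the same way.
#'
#' @param boxes a data frame containing the four box columns (extra columns
#'   are carried through).
#' @param width,height positive image dimensions in pixels.
#' @param policy \code{"clip"} (default) or \code{"drop"}.
#' @return the input data frame, clipped and/or filtered.
#' @export
clipBoxes <- function(boxes, width, height, policy = c("clip", "drop")) {
  policy <- match.arg(policy)
  stopifnot(is.data.frame(boxes), width > 0, height > 0)
  if (nrow(boxes) == 0L) return(boxes)
  m <- .boxMatrix(boxes)
  cl <- m
  cl[, c("x_min", "x_max")] <- pmin(pmax(cl[, c("x_min", "x_max")], 0), width)
  cl[, c("y_min", "y_max")] <- pmin(pmax(cl[, c("y_min", "y_max")], 0), height)
  degenerate <- cl[, "x_min"] >= cl[, "x_max"] | cl[, "y_min"] >= cl[, "y_max"]
  if (policy == "clip") {
    boxes[.BOX_COLS] <- as.data.frame(cl)
    keep <- !degenerate
  } else {
    keep <- !degenerate & apply(m == cl, 1L, all)
  }
  if (any(!keep))
    message(sum(!keep), " degenerate/out-of-bounds box(es) removed")
  boxes[keep, , drop = FALSE]
}
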