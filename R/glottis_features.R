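# Probability-map thresholding and glottis landmark extraction.

#' Binarize a probability map
#'
#' A pixel is foreground iff its probability strictly exceeds the
#' threshold. At the standard 0.5 threshold this yields the glottis mask;
#' at a very small threshold (default elsewhere: 1e-20) the mask also
#' uncovers the weakly-activated vocal-fold region.
#'
#' @param p numeric matrix of per-pixel probabilities in [0, 1].
#' @param threshold scalar strictly inside (0, 1), or any positive value
#'   below 1 (low-threshold mining uses values such as 1e-20).
#' @return Logical matrix of the same shape.
#' @export
binarize <- function(p, threshold) {
  stopifnot_scalar(threshold, "threshold")
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must lie strictly inside (0, 1)")
  p > threshold
}

#' Glottis landmarks
#'
#' Extracts the top, bottom and middle points of a glottis mask and the
#' glottal axis angle. The top (bottom) point is the midpoint of the
#' topmost (bottommost) mask row's run of foreground pixels; the middle
#' point is the pixel centroid, which is robust to asymmetric lens shapes.
#' The axis angle is that of the top-to-bottom segment measured in degrees
#' from the image vertical (positive when the bottom lies at larger x than
#' the top).
#'
#' @param mask logical matrix; must contain at least one `TRUE` pixel.
#' @return A list of class `glottis_landmarks` with `top`, `bottom`,
#'   `middle` (each `c(x, y)` in 0-based pixel-center coordinates) and
#'   `axis_angle` in degrees.
#' @export
glottis_landmarks <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0)
    stop(closed_glottis_error("glottis mask is empty"))
  rows <- idx[, 1]
  row_mid <- function(r) {
    cols <- idx[rows == r, 2]
    c((min(cols) + max(cols)) / 2 - 1, r - 1)
  }
  top <- row_mid(min(rows))
  bottom <- row_mid(max(rows))
  middle <- c(mean(idx[, 2]) - 1, mean(idx[, 1]) - 1)
  d <- bottom - top
  angle <- if (all(d == 0)) 0 else atan2(d[1], d[2]) * 180 / pi
  structure(list(top = top, bottom = bottom, middle = middle,
                 axis_angle = angle),
            class = "glottis_landmarks")
}

#' Closed-glottis condition
#'
#' Error signalled when an operation requires a non-empty glottis mask;
#' callers catch it to flag the frame rather than abort a batch.
#' @param message error message.
#' @export
closed_glottis_error <- function(message = "closed glottis") {
  structure(class = c("closed_glottis_error", "error", "condition"),
            list(message = message, call = sys.call(-1)))
}
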