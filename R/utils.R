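# Shared geometry and raster helpers.
#
# Conventions used throughout the package:
#   * images and masks are R matrices indexed [row, col];
#   * continuous coordinates are 0-based pixel centers with
#     x = column index - 1 (rightward) and y = row index - 1 (downward);
#   * boxes are numeric vectors c(x_min, y_min, x_max, y_max) in those
#     continuous coordinates.

#' Construct a bounding box
#'
#' @param x_min,y_min,x_max,y_max continuous pixel coordinates.
#' @return A named numeric vector of class `vf_box`.
#' @export
vf_box <- function(x_min, y_min, x_max, y_max) {
  if (x_min > x_max || y_min > y_max)
    stop("invalid box: min corner must not exceed max corner")
  structure(c(x_min = x_min, y_min = y_min, x_max = x_max, y_max = y_max),
            class = "vf_box")
}

box_area <- function(box) {
  if (is.null(box)) return(0)
  (box[["x_max"]] - box[["x_min"]]) * (box[["y_max"]] - box[["y_min"]])
}

box_iou <- function(a, b) {
  ix <- max(0, min(a[["x_max"]], b[["x_max"]]) - max(a[["x_min"]], b[["x_min"]]))
  iy <- max(0, min(a[["y_max"]], b[["y_max"]]) - max(a[["y_min"]], b[["y_min"]]))
  inter <- ix * iy
  un <- box_area(a) + box_area(b) - inter
  if (un <= 0) return(0)
  inter / un
}

#' Bounding box of the true pixels of a mask
#'
#' Uses 0-based pixel-center coordinates.
#' @param mask logical matrix.
#' @return A `vf_box`, or `NULL` when the mask is empty.
#' @export
mask_box <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) return(NULL)
  vf_box(min(idx[, 2]) - 1, min(idx[, 1]) - 1,
         max(idx[, 2]) - 1, max(idx[, 1]) - 1)
}

# Continuous coordinate grids for an H x W image: X[r, c] = c - 1, Y[r, c] = r - 1.
coord_grid <- function(height, width) {
  list(x = matrix(rep(0:(width - 1), each = height), height, width),
       y = matrix(rep(0:(height - 1), times = width), height, width))
}

# Nearest-pixel matrix indices for continuous points; returns NA when out
# of bounds. Half-integers round up consistently (floor(x + 0.5)) so that
# 1-px marching from half-integer coordinates visits every pixel exactly
# once (round() would round half to even and sample pixels twice).
nearest_index <- function(x, y, height, width) {
  r <- floor(y + 0.5) + 1
  c <- floor(x + 0.5) + 1
  bad <- r < 1 | r > height | c < 1 | c > width | !is.finite(r) | !is.finite(c)
  r[bad] <- NA_integer_
  c[bad] <- NA_integer_
  cbind(r, c)
}

# Logical lookup of mask values at continuous points (FALSE outside the image).
mask_at <- function(mask, x, y) {
  idx <- nearest_index(x, y, nrow(mask), ncol(mask))
  v <- rep(FALSE, length(x))
  ok <- !is.na(idx[, 1])
  v[ok] <- mask[cbind(idx[ok, 1], idx[ok, 2])]
  v
}

# Bilinear interpolation of a numeric image at continuous points.
# Points outside the image are clamped to the border.
bilinear_at <- function(img, x, y) {
  h <- nrow(img); w <- ncol(img)
  x <- pmin(pmax(x, 0), w - 1)
  y <- pmin(pmax(y, 0), h - 1)
  x0 <- floor(x); y0 <- floor(y)
  x1 <- pmin(x0 + 1, w - 1); y1 <- pmin(y0 + 1, h - 1)
  fx <- x - x0; fy <- y - y0
  i00 <- cbind(y0 + 1, x0 + 1); i01 <- cbind(y0 + 1, x1 + 1)
  i10 <- cbind(y1 + 1, x0 + 1); i11 <- cbind(y1 + 1, x1 + 1)
  img[i00] * (1 - fx) * (1 - fy) + img[i01] * fx * (1 - fy) +
    img[i10] * (1 - fx) * fy + img[i11] * fx * fy
}

# Evaluate expr with a private RNG state so callers' streams are untouched.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(expr)
}

# Matrix <-> EBImage transposition: EBImage stores (x, y), we store [row, col].
as_ebimage <- function(m) EBImage::Image(t(m))
from_ebimage <- function(img) t(EBImage::imageData(img))

stopifnot_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name))
  invisible(x)
}
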