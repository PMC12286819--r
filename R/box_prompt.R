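# Box-prompt construction: CLAHE mask fusion, pose normalization,
# morphological closing with glottis-guided contour selection, and box
# averaging with the detector output.

#' Rigid transform (rotation about a center plus translation)
#'
#' Applies `p' = R(angle) (p - center) + center + translation`, with the
#' rotation matrix acting on (x, y) image coordinates (y down). Making a
#' glottal axis of angle `theta` (degrees from vertical) vertical therefore
#' uses `angle = theta` in this convention.
#'
#' @param angle rotation angle in degrees.
#' @param center rotation center `c(x, y)`.
#' @param translation translation vector `c(dx, dy)`.
#' @return A list of class `rigid_transform`.
#' @export
rigid_transform <- function(angle = 0, center = c(0, 0),
                            translation = c(0, 0)) {
  structure(list(angle = angle, center = as.numeric(center),
                 translation = as.numeric(translation)),
            class = "rigid_transform")
}

rot_mat <- function(angle_deg) {
  a <- angle_deg * pi / 180
  matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
}

#' Apply a rigid transform to points
#'
#' @param points numeric matrix with columns (x, y), or a length-2 vector.
#' @param tf `rigid_transform`.
#' @param inverse apply the inverse transform instead.
#' @return Transformed points, same shape as input.
#' @export
apply_transform <- function(points, tf, inverse = FALSE) {
  vec <- is.null(dim(points))
  p <- if (vec) matrix(points, 1, 2) else as.matrix(points)
  if (inverse) {
    q <- sweep(p, 2, tf$center + tf$translation)
    q <- q %*% t(rot_mat(-tf$angle))
    q <- sweep(q, 2, tf$center, `+`)
  } else {
    q <- sweep(p, 2, tf$center)
    q <- q %*% t(rot_mat(tf$angle))
    q <- sweep(q, 2, tf$center + tf$translation, `+`)
  }
  if (vec) as.numeric(q) else q
}

# Resample a logical mask under a rigid transform (nearest neighbor):
# output pixel p' takes the input value at inverse(p').
resample_mask <- function(mask, tf) {
  h <- nrow(mask); w <- ncol(mask)
  grid <- coord_grid(h, w)
  src <- apply_transform(cbind(as.vector(grid$x), as.vector(grid$y)),
                         tf, inverse = TRUE)
  matrix(mask_at(mask, src[, 1], src[, 2]), h, w)
}

#' Contrast-limited adaptive histogram equalization
#'
#' Local contrast enhancement used to mine additional vocal-fold evidence
#' from the probability network. Input and output are 8-bit gray matrices.
#' The image is padded by edge replication to a multiple of the tile grid
#' before equalization and cropped back afterwards.
#'
#' @param image numeric matrix with values in [0, 255].
#' @param clip_limit contrast clip limit (as in standard CLAHE).
#' @param tile_grid integer `c(rows, cols)` of contextual tiles.
#' @return Numeric matrix in [0, 255], same shape as the input.
#' @export
clahe_enhance <- function(image, clip_limit = 2.0, tile_grid = c(8, 8)) {
  if (any(tile_grid < 1)) stop("tile_grid dimensions must be positive")
  if (stats::sd(image) == 0) return(image)  # nothing to equalize
  h <- nrow(image); w <- ncol(image)
  ph <- ceiling(h / tile_grid[1]) * tile_grid[1]
  pw <- ceiling(w / tile_grid[2]) * tile_grid[2]
  padded <- image[pmin(1:ph, h), pmin(1:pw, w), drop = FALSE]
  out <- EBImage::clahe(as_ebimage(padded / 255),
                        nx = tile_grid[2], ny = tile_grid[1],
                        limit = clip_limit, keep.range = TRUE)
  res <- from_ebimage(out)[1:h, 1:w, drop = FALSE] * 255
  pmin(pmax(res, 0), 255)
}

#' Merge two masks inside a box
#'
#' Pixels whose centers fall inside the box take the enhanced mask's
#' values; everything else keeps the base mask. With no box the base mask
#' is returned unchanged, so CLAHE-derived noise never leaks outside the
#' detector's region of interest.
#'
#' @param base,enhanced logical matrices of identical shape.
#' @param box optional `vf_box`.
#' @return Logical matrix.
#' @export
merge_masks_in_box <- function(base, enhanced, box = NULL) {
  if (!all(dim(base) == dim(enhanced))) stop("mask shapes differ")
  if (is.null(box)) return(base)
  grid <- coord_grid(nrow(base), ncol(base))
  inside <- grid$x >= box[["x_min"]] & grid$x <= box[["x_max"]] &
            grid$y >= box[["y_min"]] & grid$y <= box[["y_max"]]
  out <- base
  out[inside] <- enhanced[inside]
  out
}

#' Normalize the glottal pose
#'
#' Rotates the mask so the glottal axis becomes vertical and translates
#' the glottis middle point to the image center, compensating camera
#' shooting angle. Nearest-neighbor resampling preserves binarity.
#'
#' @param mask logical matrix.
#' @param landmarks `glottis_landmarks` of the frame's glottis mask.
#' @param image_center target center `c(x, y)`; defaults to the mask's
#'   geometric center.
#' @return List with the resampled `mask` and the `transform` used.
#' @export
normalize_pose <- function(mask, landmarks,
                           image_center = c((ncol(mask) - 1) / 2,
                                            (nrow(mask) - 1) / 2)) {
  tf <- rigid_transform(angle = landmarks$axis_angle,
                        center = landmarks$middle,
                        translation = image_center - landmarks$middle)
  list(mask = resample_mask(mask, tf), transform = tf)
}

#' Close a mask and select the glottis-bearing contour
#'
#' Applies morphological closing (elliptical structuring element) to the
#' union of the candidate mask and the glottis mask, connecting separate
#' but close components, then selects among the filled connected regions
#' the one that encompasses the glottis: a region containing at least 99%
#' of the glottis pixels (largest such region on ties), otherwise the
#' largest region overlapping the glottis, otherwise the glottis dilated
#' by the kernel radius.
#'
#' @param mask logical matrix (low-threshold fold evidence).
#' @param glottis logical matrix, non-empty.
#' @param kernel_radius radius of the closing element in pixels.
#' @return Logical matrix: the selected filled region.
#' @export
close_and_select_contour <- function(mask, glottis, kernel_radius = 5) {
  if (!all(dim(mask) == dim(glottis))) stop("mask shapes differ")
  n_glottis <- sum(glottis)
  if (n_glottis == 0) stop(closed_glottis_error("empty glottis mask"))
  brush <- EBImage::makeBrush(2 * round(kernel_radius) + 1, shape = "disc")
  closed <- from_ebimage(EBImage::closing(as_ebimage(mask | glottis), brush)) > 0
  lab <- from_ebimage(EBImage::bwlabel(EBImage::fillHull(as_ebimage(closed))))
  n_lab <- max(lab)
  if (n_lab == 0)  # cannot happen with a non-empty glottis, kept defensive
    return(from_ebimage(EBImage::dilate(as_ebimage(glottis), brush)) > 0)
  overlap <- tabulate(lab[glottis], nbins = n_lab)
  areas <- tabulate(lab[lab > 0], nbins = n_lab)
  containing <- which(overlap >= 0.99 * n_glottis)
  pick <- if (length(containing) > 0) {
    containing[which.max(areas[containing])]
  } else if (any(overlap > 0)) {
    cand <- which(overlap > 0)
    cand[which.max(areas[cand])]
  } else {
    return(from_ebimage(EBImage::dilate(as_ebimage(glottis), brush)) > 0)
  }
  lab == pick
}

#' Bounding box of a region mapped back to the original frame
#'
#' The region was selected in the pose-normalized frame; its true pixels
#' are mapped through the inverse of the normalizing transform and the
#' axis-aligned bounding box of the mapped points is returned, so the box
#' shares the original frame's coordinate system with the detector box.
#'
#' @param region logical matrix, non-empty.
#' @param transform the `rigid_transform` used for pose normalization.
#' @return A `vf_box`.
#' @export
region_box <- function(region, transform) {
  idx <- which(region, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("empty region")
  pts <- apply_transform(cbind(idx[, 2] - 1, idx[, 1] - 1),
                         transform, inverse = TRUE)
  vf_box(min(pts[, 1]), min(pts[, 2]), max(pts[, 1]), max(pts[, 2]))
}

#' Average two boxes corner-wise
#'
#' @param a `vf_box`.
#' @param b optional `vf_box`; when absent (detector failure) `a` is
#'   returned unchanged.
#' @return A `vf_box`.
#' @export
average_boxes <- function(a, b = NULL) {
  if (is.null(b)) return(a)
  vf_box((a[["x_min"]] + b[["x_min"]]) / 2, (a[["y_min"]] + b[["y_min"]]) / 2,
         (a[["x_max"]] + b[["x_max"]]) / 2, (a[["y_max"]] + b[["y_max"]]) / 2)
}

# Detector boxes that are absent or degenerate (area below 25 px^2) are
# ignored: the detector's known failure modes make tiny boxes untrustworthy.
sanitize_detector_box <- function(box, min_area = 25) {
  if (is.null(box)) return(NULL)
  if (box_area(box) < min_area) return(NULL)
  box
}

#' End-to-end box-prompt construction
#'
#' Fuses the low-threshold mask of the raw frame (base) with the
#' low-threshold mask of the CLAHE-enhanced frame inside the detector box,
#' adds the glottis mask, normalizes the pose, closes and selects the
#' glottis-bearing contour, maps its bounding box back to the original
#' frame and averages it with the detector box.
#'
#' @param base low-threshold mask from the raw frame (logical matrix).
#' @param enhanced optional low-threshold mask from the CLAHE frame.
#' @param glottis glottis mask (0.5 threshold), non-empty.
#' @param landmarks `glottis_landmarks` of `glottis`.
#' @param detector_box optional `vf_box` from the detector.
#' @param kernel_radius closing-element radius in pixels.
#' @return List with `box` (`vf_box`), `transform`, and the selected
#'   `region` in the normalized frame.
#' @export
build_box_prompt <- function(base, enhanced = NULL, glottis, landmarks,
                             detector_box = NULL, kernel_radius = 5) {
  det <- sanitize_detector_box(detector_box)
  merged <- if (is.null(enhanced)) base else
    merge_masks_in_box(base, enhanced, det)
  merged <- merged | glottis
  np <- normalize_pose(merged, landmarks)
  glottis_norm <- resample_mask(glottis, np$transform)
  region <- close_and_select_contour(np$mask, glottis_norm, kernel_radius)
  box <- region_box(region, np$transform)
  list(box = average_boxes(box, det), own_box = box,
       transform = np$transform, region = region)
}

#' Detector training label from a glottis mask
#'
#' Emits the record used to train a rough vocal-fold detector: the glottis
#' bounding box dilated by a margin ("a few dozen pixels") on every side,
#' clipped to the image, in normalized YOLO form
#' `(class, cx, cy, w, h)` with class 0.
#'
#' @param glottis logical matrix, non-empty.
#' @param margin dilation margin in pixels (> 0).
#' @param image_size `c(height, width)`; defaults to the mask's shape.
#' @return Numeric vector `c(class, cx, cy, w, h)` with entries in [0, 1]
#'   (class is 0), or `NULL` for an empty mask.
#' @export
make_detector_labels <- function(glottis, margin = 30,
                                 image_size = dim(glottis)) {
  if (margin <= 0) stop("margin must be positive")
  b <- mask_box(glottis)
  if (is.null(b)) return(NULL)
  h <- image_size[1]; w <- image_size[2]
  x0 <- max(b[["x_min"]] - margin, 0); y0 <- max(b[["y_min"]] - margin, 0)
  x1 <- min(b[["x_max"]] + margin, w); y1 <- min(b[["y_max"]] + margin, h)
  c(class = 0, cx = (x0 + x1) / 2 / w, cy = (y0 + y1) / 2 / h,
    w = (x1 - x0) / w, h = (y1 - y0) / h)
}
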