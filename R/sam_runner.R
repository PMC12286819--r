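# Iterative prompting of a pluggable promptable-segmentation backend and
# assembly of the labeled frame result.
#
# A backend is any function with signature
#   backend(image, points = NULL, box = NULL, mask_logits = NULL)
# returning list(mask = logical matrix, logits = numeric matrix,
# score = numeric scalar). Adapters for real promptable-segmentation
# checkpoints plug in behind this contract; the package ships two
# deterministic mock backends for testing.

#' Pipeline configuration
#'
#' Defaults follow the best-performing configuration of the method:
#' low threshold 1e-20, CLAHE enabled, detector fusion enabled, two
#' prompting iterations.
#'
#' @param low_threshold probability threshold that uncovers the fold
#'   region in the network output.
#' @param glottis_threshold standard threshold for the glottis mask.
#' @param clahe whether to mine a second mask from the CLAHE-enhanced
#'   frame.
#' @param clahe_clip,clahe_tiles CLAHE clip limit and tile grid.
#' @param kernel_radius closing-element radius (box stage), pixels.
#' @param iterations backend prompting iterations k (>= 1).
#' @param smooth_window,prominence point-stage smoothing window and
#'   extremum prominence (gray per pixel).
#' @param prompt_mode one of `"full"`, `"box_only"`, `"points_only"`,
#'   `"none"` (the prompt-ablation conditions).
#' @param include_glottis_points whether the three glottis landmark points
#'   join the point prompt (the glottal gap is not fold tissue; default
#'   keeps them, as the method prescribes).
#' @param keep_glottis_in_vf if `TRUE` the glottal gap is not subtracted
#'   from the fold mask before the left/right split.
#' @param detector_margin margin for detector training labels, pixels.
#' @return A list of class `vf_config`.
#' @export
vf_config <- function(low_threshold = 1e-20, glottis_threshold = 0.5,
                      clahe = TRUE, clahe_clip = 2.0, clahe_tiles = c(8, 8),
                      kernel_radius = 5, iterations = 2,
                      smooth_window = 5, prominence = 1.0,
                      prompt_mode = c("full", "box_only", "points_only", "none"),
                      include_glottis_points = TRUE,
                      keep_glottis_in_vf = FALSE,
                      detector_margin = 30) {
  prompt_mode <- match.arg(prompt_mode)
  if (iterations < 1) stop("iterations must be >= 1")
  structure(list(low_threshold = low_threshold,
                 glottis_threshold = glottis_threshold,
                 clahe = clahe, clahe_clip = clahe_clip,
                 clahe_tiles = clahe_tiles,
                 kernel_radius = kernel_radius, iterations = iterations,
                 smooth_window = smooth_window, prominence = prominence,
                 prompt_mode = prompt_mode,
                 include_glottis_points = include_glottis_points,
                 keep_glottis_in_vf = keep_glottis_in_vf,
                 detector_margin = detector_margin),
            class = "vf_config")
}

#' Iterative backend prompting
#'
#' Iteration 1 passes the points only and obtains a rough mask (logits);
#' iterations 2..k-1 pass points plus the previous logits; the final
#' iteration adds the box prompt. With k = 1 the single call carries both
#' points and box.
#'
#' @param backend a backend function (see module header).
#' @param image numeric gray matrix.
#' @param points `point_prompt_set` (>= 1 point).
#' @param box `vf_box` prompt.
#' @param k number of iterations (>= 1).
#' @return List with final `mask`, `logits`, and `score`.
#' @export
run_iterative <- function(backend, image, points, box, k = 2) {
  if (k < 1) stop("k must be >= 1")
  if (is.null(points) || nrow(points) < 1) stop("at least one point required")
  logits <- NULL
  res <- NULL
  for (i in seq_len(k)) {
    last <- i == k
    res <- backend(image,
                   points = points,
                   box = if (last) box else NULL,
                   mask_logits = if (i > 1) logits else NULL)
    logits <- res$logits
  }
  res
}

#' Split a vocal-fold mask into left and right folds
#'
#' Removes the glottal gap from the fold mask and partitions the remaining
#' pixels by the infinite line through the top and bottom glottis
#' landmarks (the glottal midline). A signed-area test against the
#' top-to-bottom direction assigns sides; pixels exactly on the line go
#' left.
#'
#' @param vf_mask logical vocal-fold mask (backend output).
#' @param glottis logical glottis mask.
#' @param landmarks `glottis_landmarks`.
#' @return List with logical `left` and `right` masks.
#' @export
split_left_right <- function(vf_mask, glottis, landmarks) {
  vf <- vf_mask & !glottis
  if (!any(vf)) {
    empty <- matrix(FALSE, nrow(vf_mask), ncol(vf_mask))
    return(list(left = empty, right = empty))
  }
  d <- landmarks$bottom - landmarks$top
  if (all(d == 0)) d <- c(0, 1)
  grid <- coord_grid(nrow(vf), ncol(vf))
  # cross product z-component of (p - top) against axis direction:
  # z >= 0 places p on the smaller-x (left) side for a downward axis.
  z <- d[1] * (grid$y - landmarks$top[2]) - d[2] * (grid$x - landmarks$top[1])
  list(left = vf & z >= 0, right = vf & z < 0)
}

#' Segment a single frame
#'
#' Runs the full pipeline: glottis mask at the standard threshold,
#' low-threshold mask mining (with CLAHE fusion inside the detector box),
#' pose-normalized closing and contour selection for the box prompt,
#' derivative-extrema point prompts, iterative backend prompting, and the
#' left/right midline split. Stage failures are caught and flagged in the
#' result rather than raised, so batch runs survive bad frames.
#'
#' @param image numeric gray matrix (8-bit range).
#' @param prob_provider function(image) returning a probability matrix in
#'   [0, 1] (a glottis network adapter; networks emitting logits must
#'   apply the sigmoid first).
#' @param detector function(image) returning a `vf_box` or `NULL`.
#' @param backend a segmentation backend (see module header).
#' @param config `vf_config`.
#' @return A list of class `frame_result`: integer `labels` matrix
#'   (0 background, 1 glottis, 2 left fold, 3 right fold), logical
#'   `glottis`/`left`/`right` masks, `prompts` (points, box), `closed`
#'   and `ok` flags, and `diagnostics`.
#' @export
segment_frame <- function(image, prob_provider, detector, backend,
                          config = vf_config()) {
  empty <- matrix(FALSE, nrow(image), ncol(image))
  result <- function(glottis = empty, left = empty, right = empty,
                     prompts = list(points = NULL, box = NULL),
                     closed = FALSE, ok = TRUE, diagnostics = list()) {
    labels <- matrix(0L, nrow(image), ncol(image))
    labels[glottis] <- 1L
    labels[left] <- 2L
    labels[right] <- 3L
    structure(list(labels = labels, glottis = glottis, left = left,
                   right = right, prompts = prompts, closed = closed,
                   ok = ok, diagnostics = diagnostics),
              class = "frame_result")
  }
  diag <- list(low_threshold = config$low_threshold,
               iterations = config$iterations,
               prompt_mode = config$prompt_mode)
  tryCatch({
    pmap <- prob_provider(image)
    glottis <- binarize(pmap, config$glottis_threshold)
    if (!any(glottis))
      return(result(closed = TRUE,
                    diagnostics = c(diag, list(reason = "closed glottis"))))
    landmarks <- glottis_landmarks(glottis)
    det_box <- sanitize_detector_box(detector(image))
    base <- binarize(pmap, config$low_threshold)
    enhanced <- NULL
    if (isTRUE(config$clahe)) {
      enh_img <- clahe_enhance(image, config$clahe_clip, config$clahe_tiles)
      enhanced <- binarize(prob_provider(enh_img), config$low_threshold)
    }
    bp <- build_box_prompt(base, enhanced, glottis, landmarks,
                           detector_box = det_box,
                           kernel_radius = config$kernel_radius)
    points <- extract_point_prompts(image, glottis, landmarks,
                                    smooth_window = config$smooth_window,
                                    prominence = config$prominence)
    if (!config$include_glottis_points)
      points <- points[!grepl("^glottis-", points$provenance), , drop = FALSE]
    diag <- c(diag, list(box = bp$box, detector_box = det_box,
                         n_points = nrow(points)))
    seg <- switch(config$prompt_mode,
      full = run_iterative(backend, image, points, bp$box,
                           k = config$iterations),
      box_only = backend(image, points = NULL, box = bp$box),
      points_only = {
        logits <- NULL; res <- NULL
        for (i in seq_len(config$iterations)) {
          res <- backend(image, points = points,
                         mask_logits = if (i > 1) logits else NULL)
          logits <- res$logits
        }
        res
      },
      none = backend(image))
    vf <- seg$mask
    lr <- if (config$keep_glottis_in_vf)
      split_left_right(vf, empty, landmarks)
    else
      split_left_right(vf, glottis, landmarks)
    result(glottis = glottis, left = lr$left, right = lr$right,
           prompts = list(points = points, box = bp$box),
           diagnostics = c(diag, list(score = seg$score)))
  },
  closed_glottis_error = function(e)
    result(closed = TRUE, diagnostics = c(diag, list(reason = conditionMessage(e)))),
  error = function(e)
    result(ok = FALSE, diagnostics = c(diag, list(error = conditionMessage(e)))))
}

#' Segment a frame sequence
#'
#' Independent per-frame processing (per-frame prompting); errors and
#' closed-glottis frames are flagged per frame, never propagated.
#'
#' @param images list of gray matrices.
#' @param prob_provider,detector,backend,config as in [segment_frame()].
#' @return List of `frame_result`.
#' @export
segment_sequence <- function(images, prob_provider, detector, backend,
                             config = vf_config()) {
  if (length(images) < 1) stop("at least one frame required")
  lapply(images, segment_frame, prob_provider = prob_provider,
         detector = detector, backend = backend, config = config)
}

# ---- Mock backends ---------------------------------------------------------

#' Oracle mock backend for a phantom frame
#'
#' Returns the ground-truth fold-plus-glottis region iff the box prompt
#' overlaps the true region box with IoU >= 0.5 and every prompt point
#' lies inside the true region; otherwise returns the box interior (empty
#' when no box is given). Boundary prompt points sit on region edges by
#' construction, so membership is checked against the region dilated by
#' two pixels (the boundary extractor's own accuracy scale).
#' Deterministic; used to test prompt quality end-to-end without model
#' weights.
#'
#' @param frame `phantom_frame` supplying the ground truth.
#' @return A backend function.
#' @export
oracle_backend <- function(frame) {
  gt <- frame$gt_glottis | frame$gt_left_fold | frame$gt_right_fold
  gt_box <- mask_box(gt)
  gt_tol <- from_ebimage(EBImage::dilate(as_ebimage(gt),
                                         EBImage::makeBrush(5, "box"))) > 0
  force(gt); force(gt_box); force(gt_tol)
  function(image, points = NULL, box = NULL, mask_logits = NULL) {
    h <- nrow(image); w <- ncol(image)
    box_ok <- !is.null(box) && !is.null(gt_box) && box_iou(box, gt_box) >= 0.5
    pts_ok <- is.null(points) || nrow(points) == 0 ||
      all(mask_at(gt_tol, points$x, points$y))
    if (box_ok && pts_ok) {
      mask <- gt
      score <- 0.95
    } else if (!is.null(box)) {
      grid <- coord_grid(h, w)
      mask <- grid$x >= box[["x_min"]] & grid$x <= box[["x_max"]] &
              grid$y >= box[["y_min"]] & grid$y <= box[["y_max"]]
      score <- 0.5
    } else {
      mask <- matrix(FALSE, h, w)
      score <- 0.1
    }
    list(mask = mask, logits = ifelse(mask, 4, -4), score = score)
  }
}

#' Box-fill mock backend
#'
#' Returns the pixels brighter than the Otsu threshold inside the box
#' prompt (whole image when no box is given) — a crude stand-in that
#' prefers the bright fold bands over the dark glottis and background.
#' Deterministic.
#'
#' @return A backend function.
#' @export
boxfill_backend <- function() {
  function(image, points = NULL, box = NULL, mask_logits = NULL) {
    h <- nrow(image); w <- ncol(image)
    thr <- EBImage::otsu(as_ebimage(image / 255)) * 255
    mask <- image > thr
    if (!is.null(box)) {
      grid <- coord_grid(h, w)
      inside <- grid$x >= box[["x_min"]] & grid$x <= box[["x_max"]] &
                grid$y >= box[["y_min"]] & grid$y <= box[["y_max"]]
      mask <- mask & inside
    }
    list(mask = mask, logits = ifelse(mask, 4, -4), score = 0.5)
  }
}
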