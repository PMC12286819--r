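test_that("CLAHE output is bounded and raises contrast on low-contrast input", {
  flat <- matrix(120, 64, 64)
  expect_equal(clahe_enhance(flat), flat)

  fr <- generate_frame(small_params(noise_sd = 3,
                                    bg_level = 90, fold_level = 120,
                                    glottis_level = 70), 0)
  out <- clahe_enhance(fr$image)
  expect_equal(dim(out), dim(fr$image))
  expect_true(all(out >= 0 & out <= 255))
  expect_gt(sd(out), sd(fr$image))

  # non-multiple-of-tile sizes are handled via padding
  odd <- fr$image[1:77, 1:63]
  expect_equal(dim(clahe_enhance(odd)), dim(odd))

  expect_error(clahe_enhance(fr$image, tile_grid = c(0, 8)), "tile_grid")
})

test_that("mask fusion only touches pixels inside the box", {
  base <- matrix(FALSE, 20, 20); base[1:6, ] <- TRUE        # 120 px
  enhanced <- matrix(FALSE, 20, 20); enhanced[1:10, ] <- TRUE  # 200 px
  full <- vf_box(0, 0, 19, 19)
  expect_identical(merge_masks_in_box(base, enhanced, full), enhanced)
  expect_identical(merge_masks_in_box(base, enhanced, NULL), base)

  # box with 50 enhanced-true and 30 base-true pixels: 120 - 30 + 50 = 140
  box <- vf_box(0, 3, 9, 7)
  merged <- merge_masks_in_box(base, enhanced, box)
  expect_equal(sum(merged), 140)
  outside <- !box_mask(box, 20, 20)
  expect_identical(merged[outside], base[outside])
})

test_that("pose normalization verticalizes the axis and inverts cleanly", {
  p <- small_params(theta = 30)
  fr <- generate_frame(p, 0)
  lm <- glottis_landmarks(fr$gt_glottis)
  np <- normalize_pose(fr$gt_glottis | gt_vf(fr), lm)
  lm_norm <- glottis_landmarks(vfprompt:::resample_mask(fr$gt_glottis,
                                                        np$transform))
  expect_lt(abs(lm_norm$axis_angle), 0.5)
  center <- c((ncol(fr$image) - 1) / 2, (nrow(fr$image) - 1) / 2)
  expect_lt(max(abs(lm_norm$middle - center)), 1.5)

  # identity when already vertical and centered
  p0 <- small_params()
  fr0 <- generate_frame(p0, 0)
  np0 <- normalize_pose(fr0$gt_glottis, glottis_landmarks(fr0$gt_glottis))
  expect_lt(abs(np0$transform$angle), 1e-9)
  expect_lt(max(abs(np0$transform$translation)), 0.51)

  # round trip moves points by well under a pixel
  pts <- cbind(seq(5, 120, length.out = 40), seq(120, 5, length.out = 40))
  back <- apply_transform(apply_transform(pts, np$transform),
                          np$transform, inverse = TRUE)
  expect_lt(max(abs(back - pts)), 0.5)
})

test_that("contour selection picks the glottis-bearing component", {
  glottis <- matrix(FALSE, 60, 60); glottis[25:35, 28:32] <- TRUE

  # one blob containing the glottis
  blob <- matrix(FALSE, 60, 60); blob[20:40, 20:40] <- TRUE
  sel <- close_and_select_contour(blob, glottis, 3)
  expect_true(all(sel[blob]))

  # two far-apart blobs: only the glottis-bearing one survives; verify
  # against an exhaustive per-component containment check
  two <- blob; two[5:12, 45:55] <- TRUE
  sel2 <- close_and_select_contour(two, glottis, 3)
  lab <- vfprompt:::from_ebimage(
    EBImage::bwlabel(vfprompt:::as_ebimage(sel2 | two)))
  glab <- unique(lab[glottis & lab > 0])
  expect_length(glab, 1)
  expect_true(all(sel2[glottis]))
  expect_false(any(sel2[5:12, 45:55]))

  # a 3-px gap closes under a radius-4 kernel
  a <- matrix(FALSE, 40, 40); a[10:30, 5:15] <- TRUE
  b <- matrix(FALSE, 40, 40); b[10:30, 19:29] <- TRUE
  g <- matrix(FALSE, 40, 40); g[18:22, 10:12] <- TRUE
  merged <- close_and_select_contour(a | b, g, 4)
  expect_true(all(merged[a]) && all(merged[b]))

  expect_error(close_and_select_contour(blob, matrix(FALSE, 60, 60), 3),
               class = "closed_glottis_error")
})

test_that("contour selection always retains the glottis (randomized blobs)", {
  set.seed(401)
  for (case in 1:25) {
    m <- matrix(FALSE, 64, 64)
    for (k in seq_len(sample(2:5, 1))) {
      r0 <- sample(5:50, 1); c0 <- sample(5:50, 1)
      m[r0:min(r0 + sample(4:14, 1), 64),
        c0:min(c0 + sample(4:14, 1), 64)] <- TRUE
    }
    g <- matrix(FALSE, 64, 64)
    gr <- sample(10:45, 1); gc <- sample(10:45, 1)
    g[gr:(gr + 8), gc:(gc + 4)] <- TRUE
    sel <- close_and_select_contour(m, g, 5)
    expect_gte(sum(sel & g) / sum(g), 0.99)
  }
})

test_that("region boxes map back through the inverse transform", {
  m <- matrix(FALSE, 40, 40); m[11:21, 6:16] <- TRUE
  expect_equal(unclass(region_box(m, rigid_transform())),
               c(x_min = 5, y_min = 10, x_max = 15, y_max = 20),
               ignore_attr = TRUE)

  tf <- rigid_transform(angle = 90, center = c(19.5, 19.5))
  rotated <- vfprompt:::resample_mask(m, tf)
  bb <- region_box(rotated, tf)
  expect_lt(max(abs(unclass(bb) - c(5, 10, 15, 20))), 1)

  expect_error(region_box(matrix(FALSE, 4, 4), rigid_transform()), "empty")
})

test_that("box averaging is corner-wise with detector fallback", {
  a <- vf_box(0, 0, 10, 10)
  b <- vf_box(10, 10, 20, 20)
  expect_equal(unclass(average_boxes(a, b)),
               c(x_min = 5, y_min = 5, x_max = 15, y_max = 15),
               ignore_attr = TRUE)
  expect_identical(average_boxes(a, a), a)
  expect_identical(average_boxes(a, NULL), a)
})

test_that("detector training labels dilate, clip and normalize", {
  g <- matrix(FALSE, 100, 100); g[51:91, 41:61] <- TRUE  # box (40,50,60,90)
  rec <- make_detector_labels(g, margin = 20)
  expect_equal(unname(rec), c(0, 0.50, 0.65, 0.60, 0.70))

  rec_full <- make_detector_labels(g, margin = 50)
  expect_equal(unname(rec_full[4:5]), c(1, 1))
  expect_true(all(rec >= 0 & rec <= 1))
  expect_null(make_detector_labels(matrix(FALSE, 10, 10), margin = 5))
})

test_that("the end-to-end box pipeline contains the folds tightly", {
  for (mode in c("ok", "missing")) {
    p <- small_params(theta = 15, seed = 21)
    fr <- generate_frame(p, 0)
    pm <- emulate_probability_map(fr)
    glottis <- binarize(pm, 0.5)
    lm <- glottis_landmarks(glottis)
    det <- jittered_detection(fr, mode)
    bp <- build_box_prompt(base = binarize(pm, 1e-20),
                           enhanced = binarize(pm, 1e-20),
                           glottis = glottis, landmarks = lm,
                           detector_box = det)
    folds <- gt_vf(fr)
    expect_gte(box_coverage(bp$box, folds), 0.95)
    fold_bb <- mask_box(folds)
    expect_lte(vfprompt:::box_area(bp$box),
               2 * vfprompt:::box_area(fold_bb))
    # selected region keeps the (normalized) glottis
    gn <- vfprompt:::resample_mask(glottis, bp$transform)
    expect_gte(sum(bp$region & gn) / sum(gn), 0.99)
  }
})
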