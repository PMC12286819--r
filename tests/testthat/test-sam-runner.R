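test_that("the iterative schedule passes prompts in the prescribed order", {
  calls <- list()
  spy <- function(image, points = NULL, box = NULL, mask_logits = NULL) {
    calls[[length(calls) + 1]] <<- list(points = !is.null(points),
                                        box = !is.null(box),
                                        logits = !is.null(mask_logits))
    m <- matrix(TRUE, nrow(image), ncol(image))
    list(mask = m, logits = m * 1, score = 1)
  }
  img <- matrix(0, 16, 16)
  pts <- data.frame(x = 5, y = 5, label = 1L, provenance = "glottis-middle")
  box <- vf_box(2, 2, 10, 10)

  run_iterative(spy, img, pts, box, k = 2)
  expect_equal(calls, list(list(points = TRUE, box = FALSE, logits = FALSE),
                           list(points = TRUE, box = TRUE, logits = TRUE)))

  calls <- list()
  run_iterative(spy, img, pts, box, k = 4)
  expect_equal(vapply(calls, `[[`, logical(1), "box"),
               c(FALSE, FALSE, FALSE, TRUE))
  expect_equal(vapply(calls, `[[`, logical(1), "logits"),
               c(FALSE, TRUE, TRUE, TRUE))

  # k = 1 degenerates to points + box in one call
  boxfill <- function(image, points = NULL, box = NULL, mask_logits = NULL) {
    g <- vfprompt:::coord_grid(nrow(image), ncol(image))
    m <- g$x >= box[["x_min"]] & g$x <= box[["x_max"]] &
         g$y >= box[["y_min"]] & g$y <= box[["y_max"]]
    list(mask = m, logits = m * 1, score = 1)
  }
  out <- run_iterative(boxfill, img, pts, box, k = 1)
  expect_equal(sum(out$mask), 9 * 9)

  expect_error(run_iterative(spy, img, pts[0, ], box), "point")
})

test_that("the midline split partitions the folds", {
  fr <- generate_frame(small_params(), 0)
  lm <- glottis_landmarks(fr$gt_glottis)
  vf <- fr$gt_glottis | gt_vf(fr)
  sp <- split_left_right(vf, fr$gt_glottis, lm)
  expect_false(any(sp$left & sp$right))
  expect_identical(sp$left | sp$right, vf & !fr$gt_glottis)
  expect_lte(abs(sum(sp$left) - sum(sp$right)),
             0.02 * sum(sp$left | sp$right))
  # the split respects image left/right
  expect_lt(mean(which(sp$left, arr.ind = TRUE)[, 2]),
            mean(which(sp$right, arr.ind = TRUE)[, 2]))

  sp0 <- split_left_right(fr$gt_glottis, fr$gt_glottis, lm)
  expect_false(any(sp0$left) || any(sp0$right))
})

test_that("frames segment end-to-end with the oracle backend", {
  p <- small_params(theta = 10, noise_sd = 4, seed = 77)
  fr <- generate_frame(p, 0)
  res <- segment_frame(fr$image, phantom_provider(fr),
                       function(img) jittered_detection(fr, "ok"),
                       oracle_backend(fr))
  expect_true(res$ok)
  expect_false(res$closed)
  expect_gte(dice(gt_vf(fr), res$left | res$right), 0.95)
  expect_identical(res$glottis, fr$gt_glottis)
  # labels partition: each pixel carries exactly one label
  expect_true(all((res$glottis + res$left + res$right) ==
                  (res$labels > 0)))

  # closed glottis: flagged, folds unlabeled
  p_closed <- small_params(osc_amplitude = 12)
  frs <- generate_sequence(p_closed, 10)
  fr_c <- frs[[which(vapply(frs, function(f) sum(f$gt_glottis) == 0,
                            logical(1)))[1]]]
  res_c <- segment_frame(fr_c$image, phantom_provider(fr_c),
                         function(img) NULL, oracle_backend(fr_c))
  expect_true(res_c$closed)
  expect_false(any(res_c$left) || any(res_c$right))

  # provider failure is flagged, not raised
  res_err <- segment_frame(fr$image, function(img) stop("boom"),
                           function(img) NULL, oracle_backend(fr))
  expect_false(res_err$ok)
  expect_match(res_err$diagnostics$error, "boom")
})

test_that("ablation modes drive the backend contract as configured", {
  fr <- generate_frame(small_params(), 0)
  calls <- list()
  spy <- function(image, points = NULL, box = NULL, mask_logits = NULL) {
    calls[[length(calls) + 1]] <<- list(points = !is.null(points),
                                        box = !is.null(box))
    m <- gt_vf(fr)
    list(mask = m, logits = m * 1, score = 1)
  }
  det <- function(img) jittered_detection(fr, "ok")
  segment_frame(fr$image, phantom_provider(fr), det, spy,
                vf_config(prompt_mode = "box_only"))
  expect_length(calls, 1)
  expect_false(calls[[1]]$points)
  expect_true(calls[[1]]$box)

  calls <- list()
  segment_frame(fr$image, phantom_provider(fr), det, spy,
                vf_config(prompt_mode = "none"))
  expect_false(calls[[1]]$points || calls[[1]]$box)

  calls <- list()
  segment_frame(fr$image, phantom_provider(fr), det, spy,
                vf_config(prompt_mode = "points_only", iterations = 2))
  expect_length(calls, 2)
  expect_false(any(vapply(calls, `[[`, logical(1), "box")))
})

test_that("prompt degradation never improves oracle-backend Dice", {
  p <- small_params(noise_sd = 3, osc_amplitude = 3, seed = 5)
  frs <- generate_sequence(p, 6)
  modes <- c("full", "box_only", "points_only", "none")
  mean_dice <- vapply(modes, function(m) {
    d <- vapply(frs, function(fr) {
      res <- segment_frame(fr$image, phantom_provider(fr),
                           function(img) jittered_detection(fr, "ok"),
                           oracle_backend(fr),
                           vf_config(prompt_mode = m))
      dice(gt_vf(fr), res$left | res$right)
    }, numeric(1))
    mean(d)
  }, numeric(1))
  expect_true(all(diff(mean_dice) <= 1e-12))  # monotone non-increasing
  expect_gte(mean_dice[["full"]], 0.95)
})

test_that("sequence segmentation isolates frames and ignores order", {
  p <- small_params(noise_sd = 2, osc_amplitude = 12, seed = 31)
  frs <- generate_sequence(p, 10)
  run_one <- function(fr)
    segment_frame(fr$image, phantom_provider(fr),
                  function(img) jittered_detection(fr, "ok"),
                  oracle_backend(fr))
  # segment_sequence over identical per-frame providers
  images <- lapply(frs, `[[`, "image")
  results <- lapply(frs, run_one)
  expect_length(results, 10)
  closed_gt <- vapply(frs, function(f) sum(f$gt_glottis) == 0, logical(1))
  expect_equal(vapply(results, `[[`, logical(1), "closed"), closed_gt)

  # permutation invariance: per-frame results identical when reordered
  perm <- rev(seq_along(frs))
  results_perm <- lapply(frs[perm], run_one)
  expect_identical(results_perm[[1]]$labels, results[[10]]$labels)

  # the boxfill backend also runs the full contract
  fr <- frs[[1]]
  res_bf <- segment_frame(fr$image, phantom_provider(fr),
                          function(img) jittered_detection(fr, "ok"),
                          boxfill_backend())
  expect_true(res_bf$ok)
  expect_gt(dice(gt_vf(fr), res_bf$left | res_bf$right), 0.5)
})
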