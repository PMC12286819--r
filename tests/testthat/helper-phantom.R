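# Shared fixtures: small phantoms keep the suite fast while leaving a
# comfortable margin between glottis, folds and the image border.

small_params <- function(...) {
  defaults <- list(height = 128L, width = 128L, theta = 0, half_length = 32,
                   half_width = 8, fold_width = 13, noise_sd = 0,
                   osc_amplitude = 0, seed = 11L)
  args <- utils::modifyList(defaults, list(...))
  do.call(phantom_params, args)
}

# Pixels-in-box helper shared by box-quality checks.
box_mask <- function(box, height, width) {
  xs <- matrix(rep(0:(width - 1), each = height), height, width)
  ys <- matrix(rep(0:(height - 1), times = width), height, width)
  xs >= box[["x_min"]] & xs <= box[["x_max"]] &
    ys >= box[["y_min"]] & ys <= box[["y_max"]]
}

# Fraction of the true pixels of `mask` covered by `box`.
box_coverage <- function(box, mask) {
  sum(box_mask(box, nrow(mask), ncol(mask)) & mask) / sum(mask)
}

gt_vf <- function(frame) frame$gt_left_fold | frame$gt_right_fold

phantom_provider <- function(frame, ...) {
  pm <- emulate_probability_map(frame, ...)
  function(image) pm
}
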