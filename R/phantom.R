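# Synthetic laryngoscope phantom.
#
# The phantom renders a dark lens-shaped glottis (intersection of two
# circular arcs) flanked by two brighter vocal-fold bands on dark tissue,
# with controllable axis orientation, a sinusoidally oscillating glottal
# half-width across frames, a linear illumination gradient along the image
# diagonal and Gaussian sensor noise. Every frame carries ground-truth
# masks and analytic fold-edge coordinates derived from the continuous
# geometry, so downstream stages can be validated without real recordings.

#' Phantom parameters
#'
#' @param height,width image size in pixels.
#' @param center glottis center `c(x, y)` in continuous pixel coordinates.
#' @param theta glottal axis angle in degrees from the image vertical;
#'   positive angles tilt the top of the glottis toward smaller x.
#' @param half_length glottal half-length h along the axis, pixels.
#' @param half_width baseline glottal half-width g at the midpoint, pixels.
#' @param fold_width width w of each vocal-fold band, pixels.
#' @param bg_level,fold_level,glottis_level 8-bit gray levels; must satisfy
#'   `fold_level > bg_level > glottis_level`.
#' @param illum_slope linear illumination gradient along the image diagonal,
#'   gray per pixel.
#' @param noise_sd Gaussian noise standard deviation, gray levels.
#' @param osc_amplitude,osc_freq amplitude A (pixels) and frequency f
#'   (cycles per frame) of the glottal half-width oscillation
#'   `g(t) = g + A sin(2 pi f t)`.
#' @param seed integer seed controlling the noise realization.
#' @return A validated list of class `phantom_params`.
#' @export
phantom_params <- function(height = 160, width = 160,
                           center = c((width - 1) / 2, (height - 1) / 2),
                           theta = 0,
                           half_length = 40, half_width = 9, fold_width = 16,
                           bg_level = 60, fold_level = 150, glottis_level = 15,
                           illum_slope = 0.08, noise_sd = 4,
                           osc_amplitude = 0, osc_freq = 0.1,
                           seed = 1L) {
  p <- list(height = as.integer(height), width = as.integer(width),
            center = as.numeric(center), theta = theta,
            half_length = half_length, half_width = half_width,
            fold_width = fold_width,
            bg_level = bg_level, fold_level = fold_level,
            glottis_level = glottis_level,
            illum_slope = illum_slope, noise_sd = noise_sd,
            osc_amplitude = osc_amplitude, osc_freq = osc_freq,
            seed = as.integer(seed))
  class(p) <- "phantom_params"
  validate_phantom_params(p)
  p
}

validate_phantom_params <- function(p) {
  if (p$height < 8 || p$width < 8) stop("phantom image too small")
  if (p$half_width < 0) stop("half_width must be >= 0")
  if (p$half_width + p$fold_width >= p$width / 2)
    stop("glottis plus fold band must fit within half the image width")
  lv <- c(p$bg_level, p$fold_level, p$glottis_level)
  if (any(lv < 0 | lv > 255)) stop("intensity levels must lie in [0, 255]")
  if (!(p$fold_level > p$bg_level && p$bg_level > p$glottis_level))
    stop("intensity ordering must be fold > background > glottis")
  if (p$half_length <= 0) stop("half_length must be positive")
  if (p$fold_width <= 0) stop("fold_width must be positive")
  invisible(p)
}

# Axis direction (downward along the glottis) and its +x-oriented orthogonal.
phantom_axes <- function(theta) {
  th <- theta * pi / 180
  list(axis = c(sin(th), cos(th)), orth = c(cos(th), -sin(th)))
}

# Half-width profile of a lens with half-length h and mid half-width g,
# evaluated at signed axis positions v. Zero outside |v| <= h or when g <= 0.
lens_half_width <- function(v, h, g) {
  if (g <= 0) return(rep(0, length(v)))
  R <- (g^2 + h^2) / (2 * g)
  w <- sqrt(pmax(R^2 - v^2, 0)) - (R - g)
  w[abs(v) > h] <- 0
  pmax(w, 0)
}

phantom_half_width_at <- function(params, t) {
  params$half_width +
    params$osc_amplitude * sin(2 * pi * params$osc_freq * t)
}

#' Analytic glottal lens area at a frame index
#'
#' Area of the lens (two circular segments) in square pixels; zero when the
#' oscillation closes the glottis.
#' @param params `phantom_params`.
#' @param t 0-based frame index.
#' @export
phantom_glottis_area <- function(params, t) {
  g <- phantom_half_width_at(params, t)
  h <- params$half_length
  if (g <= 0) return(0)
  R <- (g^2 + h^2) / (2 * g)
  2 * (R^2 * acos((R - g) / R) - (R - g) * h)
}

#' Generate one phantom frame
#'
#' @param params `phantom_params`.
#' @param t 0-based frame index; drives the half-width oscillation.
#' @return A `phantom_frame`: 8-bit gray `image`, disjoint logical masks
#'   `gt_glottis`, `gt_left_fold`, `gt_right_fold`, a data frame
#'   `boundaries` with per-row analytic fold-edge x-coordinates
#'   (`left_outer`, `left_inner`, `right_inner`, `right_outer`), the
#'   effective `half_width_t`, and the generating `params` and `t`.
#' @export
generate_frame <- function(params, t = 0) {
  validate_phantom_params(params)
  h <- params$half_length
  g_t <- phantom_half_width_at(params, t)
  g_open <- max(g_t, 0)
  ax <- phantom_axes(params$theta)
  grid <- coord_grid(params$height, params$width)
  rx <- grid$x - params$center[1]
  ry <- grid$y - params$center[2]
  v <- rx * ax$axis[1] + ry * ax$axis[2]
  u <- rx * ax$orth[1] + ry * ax$orth[2]

  inner <- matrix(lens_half_width(as.vector(v), h, g_open),
                  params$height, params$width)
  in_band <- abs(v) <= h
  gt_glottis <- g_t > 0 & in_band & abs(u) <= inner
  outer <- inner + params$fold_width
  gt_left <- in_band & u < -inner & u >= -outer
  gt_right <- in_band & u > inner & u <= outer

  img <- matrix(params$bg_level, params$height, params$width)
  img <- img + params$illum_slope *
    (grid$x + grid$y - (params$width + params$height - 2) / 2) / sqrt(2)
  img[gt_left | gt_right] <- params$fold_level
  img[gt_glottis] <- params$glottis_level
  img <- round(pmin(pmax(img, 0), 255))
  if (params$noise_sd > 0) {
    noise <- with_local_seed(
      (params$seed %% 1000003L) * 2053L + t,
      matrix(stats::rnorm(length(img), 0, params$noise_sd),
             params$height, params$width))
    img <- round(pmin(pmax(img + noise, 0), 255))
  }

  structure(list(image = img,
                 gt_glottis = gt_glottis,
                 gt_left_fold = gt_left,
                 gt_right_fold = gt_right,
                 boundaries = phantom_row_boundaries(params, t),
                 half_width_t = g_t,
                 params = params, t = t),
            class = "phantom_frame")
}

#' Analytic per-row fold-edge coordinates
#'
#' For every image row intersecting the fold bands, the continuous
#' x-coordinates where the row enters and leaves each band, computed from
#' the lens geometry at sub-pixel resolution (0.05 px), independently of
#' the rasterized masks.
#' @param params `phantom_params`.
#' @param t 0-based frame index.
#' @return Data frame with columns `row`, `left_outer`, `left_inner`,
#'   `right_inner`, `right_outer` (NA where the row misses a band).
#' @export
phantom_row_boundaries <- function(params, t = 0) {
  h <- params$half_length
  g_open <- max(phantom_half_width_at(params, t), 0)
  ax <- phantom_axes(params$theta)
  xs <- seq(0, params$width - 1, by = 0.05)
  rows <- 0:(params$height - 1)
  res <- lapply(rows, function(y0) {
    rx <- xs - params$center[1]
    ry <- y0 - params$center[2]
    v <- rx * ax$axis[1] + ry * ax$axis[2]
    u <- rx * ax$orth[1] + ry * ax$orth[2]
    inner <- lens_half_width(v, h, g_open)
    in_band <- abs(v) <= h
    outer <- inner + params$fold_width
    lf <- in_band & u < -inner & u >= -outer
    rf <- in_band & u > inner & u <= outer
    if (!any(lf) && !any(rf)) return(NULL)
    rng <- function(sel) if (any(sel)) range(xs[sel]) else c(NA_real_, NA_real_)
    l <- rng(lf); r <- rng(rf)
    data.frame(row = y0, left_outer = l[1], left_inner = l[2],
               right_inner = r[1], right_outer = r[2])
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(row = integer(), left_outer = numeric(),
                      left_inner = numeric(), right_inner = numeric(),
                      right_outer = numeric())
  out
}

#' Analytic fold-edge points along axis-orthogonal scan lines
#'
#' For each fraction along the top-to-bottom glottal axis, the continuous
#' image coordinates where the orthogonal scan line crosses the four fold
#' edges. This is the oracle for boundary-point recovery.
#' @param params `phantom_params`.
#' @param t 0-based frame index.
#' @param fracs fractions in (0, 1) along the axis (top = 0).
#' @return Data frame with `frac`, `edge` (one of `left_outer`,
#'   `left_inner`, `right_inner`, `right_outer`), `x`, `y`.
#' @export
phantom_scanline_edges <- function(params, t = 0, fracs = c(0.25, 0.5, 0.75)) {
  h <- params$half_length
  g_open <- max(phantom_half_width_at(params, t), 0)
  ax <- phantom_axes(params$theta)
  out <- lapply(fracs, function(fr) {
    va <- -h + fr * 2 * h
    inner <- lens_half_width(va, h, g_open)
    outer <- inner + params$fold_width
    us <- c(left_outer = -outer, left_inner = -inner,
            right_inner = inner, right_outer = outer)
    data.frame(frac = fr, edge = names(us),
               x = params$center[1] + us * ax$orth[1] + va * ax$axis[1],
               y = params$center[2] + us * ax$orth[2] + va * ax$axis[2],
               row.names = NULL)
  })
  do.call(rbind, out)
}

#' Generate a phantom frame sequence
#'
#' @param params `phantom_params`.
#' @param n_frames number of frames (>= 1); frame t uses the oscillated
#'   half-width `g + A sin(2 pi f t)`, t = 0 .. n_frames - 1. Frames whose
#'   half-width falls to zero or below have an empty glottis mask while the
#'   fold masks remain intact (closed glottis).
#' @return List of `phantom_frame`.
#' @export
generate_sequence <- function(params, n_frames) {
  if (n_frames < 1) stop("n_frames must be >= 1")
  lapply(0:(n_frames - 1), function(t) generate_frame(params, t))
}

#' Emulate a glottis-network probability map
#'
#' Mimics the low-threshold behavior of a glottis segmentation network:
#' glottis pixels receive a high probability, vocal-fold pixels a tiny but
#' positive probability, and a seeded random fraction of background pixels
#' the same tiny value (spurious responses), so that thresholding at 0.5
#' recovers the glottis while a very low threshold uncovers the folds.
#'
#' @param frame `phantom_frame`.
#' @param glottis_level probability assigned to glottis pixels, in [0.5, 1].
#' @param fold_level probability assigned to fold pixels, in (0, 0.5).
#' @param noise_rate fraction of background pixels set to `fold_level`.
#' @param seed integer seed for the noise pixels.
#' @return Numeric matrix in [0, 1], same shape as the frame.
#' @export
emulate_probability_map <- function(frame, glottis_level = 0.95,
                                    fold_level = 1e-18, noise_rate = 0.01,
                                    seed = frame$params$seed) {
  if (!(fold_level > 0 && fold_level < 0.5 &&
        glottis_level >= 0.5 && glottis_level <= 1))
    stop("require 0 < fold_level < 0.5 <= glottis_level <= 1")
  if (noise_rate < 0 || noise_rate > 1) stop("noise_rate must be in [0, 1]")
  p <- matrix(0, nrow(frame$image), ncol(frame$image))
  folds <- frame$gt_left_fold | frame$gt_right_fold
  p[folds] <- fold_level
  p[frame$gt_glottis] <- glottis_level
  bg <- which(!folds & !frame$gt_glottis)
  n_noise <- round(noise_rate * length(bg))
  if (n_noise > 0) {
    pick <- with_local_seed(seed, sample(bg, n_noise))
    p[pick] <- fold_level
  }
  p
}

#' Fallible detector stub
#'
#' Emulates an object detector for the vocal-fold region, including its
#' failure modes: `ok` returns the ground-truth fold-region box with
#' per-corner uniform jitter, `missing` returns no box, `wrong` returns a
#' box translated by more than its own diagonal, and `small` a box scaled
#' to 0.3x about its center.
#'
#' @param frame `phantom_frame`.
#' @param mode one of `"ok"`, `"missing"`, `"wrong"`, `"small"`.
#' @param jitter maximum per-corner displacement in pixels (`ok` mode).
#' @param seed integer seed.
#' @return A `vf_box`, or `NULL` in `missing` mode.
#' @export
jittered_detection <- function(frame, mode = c("ok", "missing", "wrong", "small"),
                               jitter = 5, seed = frame$params$seed) {
  mode <- match.arg(mode)
  if (mode == "missing") return(NULL)
  region <- frame$gt_glottis | frame$gt_left_fold | frame$gt_right_fold
  tb <- mask_box(region)
  if (is.null(tb)) return(NULL)
  if (mode == "small") {
    cx <- (tb[["x_min"]] + tb[["x_max"]]) / 2
    cy <- (tb[["y_min"]] + tb[["y_max"]]) / 2
    hw <- (tb[["x_max"]] - tb[["x_min"]]) * 0.3 / 2
    hh <- (tb[["y_max"]] - tb[["y_min"]]) * 0.3 / 2
    return(vf_box(cx - hw, cy - hh, cx + hw, cy + hh))
  }
  if (mode == "wrong") {
    diag_len <- sqrt((tb[["x_max"]] - tb[["x_min"]])^2 +
                     (tb[["y_max"]] - tb[["y_min"]])^2)
    ang <- with_local_seed(seed + 7L, stats::runif(1, 0, 2 * pi))
    dx <- 1.25 * diag_len * cos(ang)
    dy <- 1.25 * diag_len * sin(ang)
    return(vf_box(tb[["x_min"]] + dx, tb[["y_min"]] + dy,
                  tb[["x_max"]] + dx, tb[["y_max"]] + dy))
  }
  d <- with_local_seed(seed + 13L, stats::runif(4, -jitter, jitter))
  xs <- sort(c(tb[["x_min"]] + d[1], tb[["x_max"]] + d[3]))
  ys <- sort(c(tb[["y_min"]] + d[2], tb[["y_max"]] + d[4]))
  vf_box(xs[1], ys[1], xs[2], ys[2])
}
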