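# Dice evaluation and mask-derived clinical waveforms: glottal midline
# geometry, vocal-fold movement (VFM), vocal-fold width (VFW), and the
# glottal area waveform (GAW).

#' Dice coefficient with epsilon guard
#'
#' `(2 |GT & Seg| + eps) / (|GT| + |Seg| + eps)` with
#' `eps = 2.2204e-16`, so two empty masks compare as identical (Dice 1).
#'
#' @param gt,seg logical matrices of identical shape.
#' @return Similarity in [0, 1].
#' @export
dice <- function(gt, seg) {
  if (!all(dim(gt) == dim(seg))) stop("mask shapes differ")
  eps <- 2.2204e-16
  (2 * sum(gt & seg) + eps) / (sum(gt) + sum(seg) + eps)
}

#' Glottal midline geometry
#'
#' Locates point D (midpoint of the bottommost glottis row's run), the
#' centroid C, and T: the last point inside the mask along the ray from D
#' through C (marched at 0.25-px steps). The segment D-T hypothesizes the
#' glottal midline; n equidistant stations C_i divide it,
#' `C_i = D + i (T - D) / (n + 1)`.
#'
#' @param glottis logical glottis mask, non-empty.
#' @param n number of stations (>= 1).
#' @return A list of class `midline_geometry` with `D`, `C`, `T` (each
#'   `c(x, y)`) and `stations` (n x 2 matrix).
#' @export
glottal_midline <- function(glottis, n = 3) {
  if (n < 1) stop("n must be >= 1")
  idx <- which(glottis, arr.ind = TRUE)
  if (nrow(idx) == 0) stop(closed_glottis_error("empty glottis mask"))
  bot_row <- max(idx[, 1])
  cols <- idx[idx[, 1] == bot_row, 2]
  D <- c((min(cols) + max(cols)) / 2 - 1, bot_row - 1)
  C <- c(mean(idx[, 2]) - 1, mean(idx[, 1]) - 1)
  dir <- C - D
  len <- sqrt(sum(dir^2))
  if (len < 1e-9) {
    # degenerate (e.g. single-pixel mask): midline collapses onto D
    Tpt <- D
  } else {
    dir <- dir / len
    max_steps <- ceiling((nrow(glottis) + ncol(glottis)) / 0.25)
    Tpt <- D
    for (k in seq_len(max_steps)) {
      p <- D + (k * 0.25) * dir
      if (!mask_at(glottis, p[1], p[2])) break
      Tpt <- p
    }
  }
  st <- t(vapply(seq_len(n), function(i) D + i * (Tpt - D) / (n + 1),
                 numeric(2)))
  structure(list(D = D, C = C, T = Tpt, stations = st),
            class = "midline_geometry")
}

#' Fold-mask intersections of midline perpendiculars
#'
#' From each midline station, marches along the perpendicular to D-T
#' toward the left and right at 1-px steps up to `max_radius`. On each
#' side, the inner point is the first fold-mask pixel met and the outer
#' point the last pixel of that contiguous run; a side with no hit is
#' absent (NA).
#'
#' @param left,right logical fold masks.
#' @param geometry `midline_geometry`.
#' @param max_radius maximum marching distance, pixels.
#' @return Data frame with `station`, `side` ("left"/"right"), signed
#'   distances `inner` and `outer` from the station (NA when absent).
#' @export
fold_intersections <- function(left, right, geometry,
                               max_radius = ncol(left) / 2) {
  d <- geometry$T - geometry$D
  len <- sqrt(sum(d^2))
  d <- if (len < 1e-9) c(0, -1) else d / len
  perp <- c(d[2], -d[1])
  if (perp[1] > 0) perp <- -perp  # orient toward decreasing x (image left)
  march <- function(mask, origin, dir) {
    inner <- NA_real_; outer <- NA_real_
    for (s in seq_len(floor(max_radius))) {
      p <- origin + s * dir
      hit <- mask_at(mask, p[1], p[2])
      if (is.na(inner)) {
        if (hit) { inner <- s; outer <- s }
      } else {
        if (hit) outer <- s else break
      }
    }
    c(inner = inner, outer = outer)
  }
  n <- nrow(geometry$stations)
  out <- lapply(seq_len(n), function(i) {
    ci <- geometry$stations[i, ]
    l <- march(left, ci, perp)
    r <- march(right, ci, -perp)
    data.frame(station = i, side = c("left", "right"),
               inner = c(l[["inner"]], r[["inner"]]),
               outer = c(l[["outer"]], r[["outer"]]))
  })
  do.call(rbind, out)
}

# Shared driver: per-frame midline + intersections over a result sequence.
waveform_frames <- function(results, n, max_radius) {
  lapply(seq_along(results), function(k) {
    res <- results[[k]]
    closed <- isTRUE(res$closed) || !isTRUE(res$ok) || !any(res$glottis)
    if (closed) return(list(frame = k - 1, missing = TRUE))
    geom <- glottal_midline(res$glottis, n)
    mr <- if (is.null(max_radius)) ncol(res$glottis) / 2 else max_radius
    list(frame = k - 1, missing = FALSE,
         inter = fold_intersections(res$left, res$right, geom, mr),
         area = sum(res$glottis))
  })
}

#' Vocal-fold movement waveform
#'
#' Per frame, station and side: the mean distance of the fold's inner and
#' outer boundary points from the midline station,
#' `(|inner| + |outer|) / 2` — the folds' deviation from the glottal
#' midline over time. Closed-glottis or failed frames are flagged missing
#' and carry NA values.
#'
#' @param results list of `frame_result` (or any objects with `glottis`,
#'   `left`, `right`, `closed`, `ok` fields).
#' @param n number of midline stations.
#' @param max_radius marching limit, pixels (default half image width).
#' @return Data frame with `frame`, `missing`, `side`, `station`,
#'   `vfm_px`.
#' @export
vfm_series <- function(results, n = 3, max_radius = NULL) {
  rows <- lapply(waveform_frames(results, n, max_radius), function(fr) {
    if (fr$missing)
      return(data.frame(frame = fr$frame, missing = TRUE,
                        side = rep(c("left", "right"), each = n),
                        station = rep(seq_len(n), 2), vfm_px = NA_real_))
    data.frame(frame = fr$frame, missing = FALSE,
               side = fr$inter$side, station = fr$inter$station,
               vfm_px = (fr$inter$inner + fr$inter$outer) / 2)
  })
  do.call(rbind, rows)
}

#' Vocal-fold width waveform
#'
#' Per frame, station and side: the gap between the inner and outer
#' boundary points, `outer - inner`. For rigid folds this stays constant
#' while the movement waveform oscillates — the stability contrast that
#' separates width from movement. Closed frames are flagged missing.
#'
#' @inheritParams vfm_series
#' @return Data frame with `frame`, `missing`, `side`, `station`,
#'   `vfw_px`.
#' @export
vfw_series <- function(results, n = 3, max_radius = NULL) {
  rows <- lapply(waveform_frames(results, n, max_radius), function(fr) {
    if (fr$missing)
      return(data.frame(frame = fr$frame, missing = TRUE,
                        side = rep(c("left", "right"), each = n),
                        station = rep(seq_len(n), 2), vfw_px = NA_real_))
    data.frame(frame = fr$frame, missing = FALSE,
               side = fr$inter$side, station = fr$inter$station,
               vfw_px = fr$inter$outer - fr$inter$inner)
  })
  do.call(rbind, rows)
}

#' Glottal area waveform
#'
#' Glottal area (pixel count of the glottis mask) per frame.
#'
#' @param glottis_masks list of logical glottis masks (or `frame_result`s,
#'   whose `glottis` field is used).
#' @return Data frame with `frame`, `missing`, `gaw_px2`.
#' @export
gaw_series <- function(glottis_masks) {
  rows <- lapply(seq_along(glottis_masks), function(k) {
    m <- glottis_masks[[k]]
    if (is.list(m)) m <- m$glottis
    data.frame(frame = k - 1, missing = FALSE, gaw_px2 = sum(m))
  })
  do.call(rbind, rows)
}

#' Combined waveform table
#'
#' One long table joining VFM, VFW and GAW, in the column layout used by
#' the `waveforms` CLI subcommand.
#'
#' @inheritParams vfm_series
#' @return Data frame with `frame`, `missing`, `side`, `station`,
#'   `vfm_px`, `vfw_px`, `gaw_px2`.
#' @export
waveform_table <- function(results, n = 3, max_radius = NULL) {
  vfm <- vfm_series(results, n, max_radius)
  vfw <- vfw_series(results, n, max_radius)
  gaw <- gaw_series(lapply(results, `[[`, "glottis"))
  out <- vfm
  out$vfw_px <- vfw$vfw_px
  out$gaw_px2 <- gaw$gaw_px2[out$frame + 1]
  out
}

#' Dominant frequency of a waveform
#'
#' Periodogram peak location (cycles per frame) of a demeaned series;
#' missing values are linearly interpolated first. Convenience for
#' oscillation-recovery checks.
#'
#' @param x numeric series (may contain NA).
#' @return Frequency in cycles/frame.
#' @export
dominant_frequency <- function(x) {
  idx <- seq_along(x)
  if (anyNA(x)) {
    ok <- !is.na(x)
    if (sum(ok) < 4) stop("too few observed values")
    x <- stats::approx(idx[ok], x[ok], xout = idx, rule = 2)$y
  }
  sp <- stats::spec.pgram(stats::ts(x - mean(x)), taper = 0, detrend = FALSE,
                          plot = FALSE)
  sp$freq[which.max(sp$spec)]
}
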