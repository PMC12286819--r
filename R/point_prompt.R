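# Point-prompt extraction: fold-boundary points from smoothed
# first-derivative extrema of the gray profile along scan lines orthogonal
# to the glottal axis, plus the three glottis landmark points.
#
# Rationale: along a left-to-right traverse, intensity rises sharply from
# shadowed tissue onto the left fold surface (derivative maximum at the
# left outer boundary) and drops sharply off the right fold back into
# shadow (derivative minimum at the right outer boundary). Scanning
# outward from the glottis, the first qualifying extremum on each side
# marks the fold's outer edge.

#' Build axis-orthogonal scan lines
#'
#' Defines scan lines through the quadrisection points (fractions 0.25,
#' 0.50, 0.75 by default) of the top-to-bottom glottal segment, all sharing
#' the direction orthogonal to the axis and oriented toward increasing x.
#' Stations are spaced 1 px along each line, out to `max_radius`, and
#' clipped to the image.
#'
#' @param landmarks `glottis_landmarks`; top and bottom must differ.
#' @param image_size `c(height, width)` used for clipping.
#' @param fracs fractions along the axis (top = 0, bottom = 1).
#' @param max_radius maximum |station| in pixels; default half the image
#'   width.
#' @return List of scan lines, each a list with `anchor` `c(x, y)`,
#'   unit `direction` `c(dx, dy)`, and numeric `stations` (signed
#'   distances; 0 is the anchor).
#' @export
build_scan_lines <- function(landmarks, image_size,
                             fracs = c(0.25, 0.50, 0.75),
                             max_radius = image_size[2] / 2) {
  d <- landmarks$bottom - landmarks$top
  len <- sqrt(sum(d^2))
  if (len == 0) stop("degenerate glottal axis: top equals bottom")
  axis_dir <- d / len
  dir <- c(axis_dir[2], -axis_dir[1])
  if (dir[1] < 0) dir <- -dir  # orient toward increasing x
  h <- image_size[1]; w <- image_size[2]
  lapply(fracs, function(fr) {
    anchor <- landmarks$top + fr * d
    s <- seq(-floor(max_radius), floor(max_radius), by = 1)
    px <- anchor[1] + s * dir[1]
    py <- anchor[2] + s * dir[2]
    keep <- px >= 0 & px <= w - 1 & py >= 0 & py <= h - 1
    list(anchor = anchor, direction = dir, stations = s[keep], frac = fr)
  })
}

#' Intensity derivative profile along a scan line
#'
#' Samples the image by bilinear interpolation at the line's 1-px-spaced
#' stations, takes the central-difference first derivative and smooths it
#' with a moving average to suppress spurious local extrema. Also locates
#' the glottis interval: the maximal run of stations inside the glottis
#' mask that contains the anchor.
#'
#' @param image numeric gray matrix.
#' @param line one scan line from [build_scan_lines()].
#' @param glottis logical glottis mask.
#' @param smooth_window odd moving-average window length (stations).
#' @return A list of class `derivative_profile` with `stations`, `gray`,
#'   `deriv` (smoothed), `glottis_interval` (index range into `stations`,
#'   or `NULL`), and the line's `anchor`/`direction`.
#' @export
derivative_profile <- function(image, line, glottis, smooth_window = 5) {
  if (smooth_window < 1 || smooth_window %% 2 == 0)
    stop("smooth_window must be odd and >= 1")
  s <- line$stations
  if (length(s) < 3) stop("scan line lies outside the image")
  px <- line$anchor[1] + s * line$direction[1]
  py <- line$anchor[2] + s * line$direction[2]
  gray <- bilinear_at(image, px, py)
  n <- length(gray)
  deriv <- numeric(n)
  deriv[2:(n - 1)] <- (gray[3:n] - gray[1:(n - 2)]) / 2
  deriv[1] <- gray[2] - gray[1]
  deriv[n] <- gray[n] - gray[n - 1]
  if (smooth_window > 1) {
    half <- (smooth_window - 1) / 2
    padded <- c(rep(deriv[1], half), deriv, rep(deriv[n], half))
    sm <- stats::filter(padded, rep(1 / smooth_window, smooth_window),
                        sides = 2)
    deriv <- as.numeric(sm[(half + 1):(half + n)])
  }
  inside <- mask_at(glottis, px, py)
  anchor_idx <- which.min(abs(s))
  interval <- NULL
  if (inside[anchor_idx]) {
    lo <- anchor_idx
    while (lo > 1 && inside[lo - 1]) lo <- lo - 1
    hi <- anchor_idx
    while (hi < n && inside[hi + 1]) hi <- hi + 1
    interval <- c(lo, hi)
  }
  structure(list(stations = s, gray = gray, deriv = deriv,
                 glottis_interval = interval,
                 anchor = line$anchor, direction = line$direction),
            class = "derivative_profile")
}

#' Fold-boundary points from a derivative profile
#'
#' Scanning outward from the glottis interval, returns the first strict
#' local maximum of the smoothed derivative on the left (the left fold's
#' outer boundary, where intensity rises from shadow onto the fold) and
#' the first strict local minimum on the right (the right fold's outer
#' boundary), each required to clear a prominence threshold. A side with
#' no qualifying extremum yields no point.
#'
#' @param profile a `derivative_profile` with a glottis interval.
#' @param prominence floor on |derivative| (gray per pixel) for a
#'   qualifying extremum. The effective threshold is the larger of this
#'   floor and three times the median absolute deviation of the smoothed
#'   derivative, so sensor noise on the fold surface does not spawn
#'   spurious boundary extrema while clean imagery keeps full
#'   sensitivity.
#' @return List with `left` and `right`, each `c(x, y)` in image
#'   coordinates or `NULL`.
#' @export
boundary_points <- function(profile, prominence = 1.0) {
  iv <- profile$glottis_interval
  if (is.null(iv))
    stop("profile has no glottis interval; drop this scan line")
  d <- profile$deriv
  n <- length(d)
  prominence <- max(prominence, 3 * stats::mad(d, center = 0))
  pt_at <- function(j) {
    s <- profile$stations[j]
    profile$anchor + s * profile$direction
  }
  # Exact plateaus (possible on noise-free imagery after smoothing) break
  # the strict comparison; a tiny tolerance keeps the plateau station
  # nearest the glottis, matching the nearest-extremum tie-break.
  tol <- 1e-6
  left <- NULL
  if (iv[1] - 1 >= 2) {
    for (j in seq(iv[1] - 1, 2, by = -1)) {
      if (d[j] > d[j - 1] - tol && d[j] > d[j + 1] - tol &&
          d[j] >= prominence) {
        while (j > 1 && abs(d[j - 1] - d[j]) <= tol) j <- j - 1
        left <- pt_at(j); break
      }
    }
  }
  right <- NULL
  if (iv[2] + 1 <= n - 1) {
    for (j in seq(iv[2] + 1, n - 1, by = 1)) {
      if (d[j] < d[j - 1] + tol && d[j] < d[j + 1] + tol &&
          d[j] <= -prominence) {
        while (j < n && abs(d[j + 1] - d[j]) <= tol) j <- j + 1
        right <- pt_at(j); break
      }
    }
  }
  list(left = left, right = right)
}

#' Assemble the point-prompt set
#'
#' Combines all found boundary points with the three glottis landmark
#' points (top, middle, bottom), all labeled foreground. With three scan
#' lines succeeding on both sides this yields the full nine-point prompt.
#'
#' @param boundaries list of per-line results from [boundary_points()].
#' @param landmarks `glottis_landmarks`.
#' @return Data frame of class `point_prompt_set` with columns `x`, `y`,
#'   `label` (1 = foreground), `provenance`.
#' @export
assemble_point_prompts <- function(boundaries, landmarks) {
  rows <- list()
  for (i in seq_along(boundaries)) {
    b <- boundaries[[i]]
    if (!is.null(b$left))
      rows[[length(rows) + 1]] <- data.frame(
        x = b$left[1], y = b$left[2], label = 1L,
        provenance = sprintf("boundary-left-%d", i))
    if (!is.null(b$right))
      rows[[length(rows) + 1]] <- data.frame(
        x = b$right[1], y = b$right[2], label = 1L,
        provenance = sprintf("boundary-right-%d", i))
  }
  lm <- list(top = landmarks$top, middle = landmarks$middle,
             bottom = landmarks$bottom)
  for (nm in names(lm))
    rows[[length(rows) + 1]] <- data.frame(
      x = lm[[nm]][1], y = lm[[nm]][2], label = 1L,
      provenance = paste0("glottis-", nm))
  out <- do.call(rbind, rows)
  class(out) <- c("point_prompt_set", class(out))
  out
}

#' Extract point prompts from a frame
#'
#' Full point-prompt stage: builds the three quadrisection scan lines,
#' computes smoothed derivative profiles, picks boundary extrema, and
#' assembles them with the glottis landmarks. Scan lines whose anchor
#' falls outside the glottis mask are dropped silently (their boundary
#' points are simply absent).
#'
#' @param image numeric gray matrix.
#' @param glottis logical glottis mask, non-empty.
#' @param landmarks optional precomputed `glottis_landmarks`.
#' @param smooth_window odd moving-average window (stations).
#' @param prominence extremum prominence threshold, gray per pixel.
#' @param fracs scan-line fractions along the glottal axis.
#' @return A `point_prompt_set` (3 to 9 points).
#' @export
extract_point_prompts <- function(image, glottis,
                                  landmarks = glottis_landmarks(glottis),
                                  smooth_window = 5, prominence = 1.0,
                                  fracs = c(0.25, 0.50, 0.75)) {
  if (all(landmarks$top == landmarks$bottom)) {
    return(assemble_point_prompts(list(), landmarks))
  }
  lines <- build_scan_lines(landmarks, dim(image), fracs = fracs)
  bounds <- lapply(lines, function(ln) {
    prof <- derivative_profile(image, ln, glottis, smooth_window)
    if (is.null(prof$glottis_interval)) return(list(left = NULL, right = NULL))
    boundary_points(prof, prominence)
  })
  assemble_point_prompts(bounds, landmarks)
}
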