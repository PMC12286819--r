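# Readers and writers: frames (PNG/TIFF), labeled masks, float-TIFF
# probability maps, YOLO-dialect detector boxes, prompt bundles (JSON),
# and CSV reports.

LABEL_CODES <- c(background = 0L, glottis = 85L, left = 170L, right = 255L)

#' Read a directory of frames
#'
#' Reads all PNG/TIFF images in lexicographic name order. RGB images are
#' converted to 8-bit luminance (ITU-R BT.601 weights); 16-bit images are
#' rescaled to the 8-bit range by their maximum representable value.
#'
#' @param path directory containing `.png`, `.tif` or `.tiff` files.
#' @return Named list of numeric gray matrices in [0, 255].
#' @export
read_frames <- function(path) {
  files <- sort(list.files(path, pattern = "\\.(png|tif|tiff)$",
                           ignore.case = TRUE, full.names = TRUE))
  if (length(files) == 0) stop("no PNG/TIFF frames found in ", path)
  frames <- lapply(files, read_gray_image)
  names(frames) <- basename(files)
  frames
}

read_gray_image <- function(file) {
  arr <- tryCatch({
    if (grepl("\\.png$", file, ignore.case = TRUE)) png::readPNG(file)
    else tiff::readTIFF(file)
  }, error = function(e) stop("unreadable image file ", file, ": ",
                              conditionMessage(e)))
  if (length(dim(arr)) == 3) {
    ch <- dim(arr)[3]
    arr <- if (ch >= 3)
      0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]
    else arr[, , 1]
  }
  arr * 255
}

#' Write an 8-bit gray frame as PNG
#'
#' @param image numeric matrix in [0, 255].
#' @param file output path.
#' @export
write_frame_png <- function(image, file) {
  png::writePNG(pmin(pmax(image, 0), 255) / 255, file)
  invisible(file)
}

#' Write / read a labeled mask
#'
#' Single-channel 8-bit encoding: 0 background, 85 glottis, 170 left
#' fold, 255 right fold. Reading a file with any other value is an error.
#'
#' @param result a `frame_result` (or an integer labels matrix with
#'   values 0-3).
#' @param file path to a PNG file.
#' @return `read_labeled_mask` returns an integer labels matrix (0-3).
#' @export
write_labeled_mask <- function(result, file) {
  labels <- if (is.list(result)) result$labels else result
  enc <- matrix(LABEL_CODES[labels + 1L], nrow(labels), ncol(labels))
  png::writePNG(enc / 255, file)
  invisible(file)
}

#' @rdname write_labeled_mask
#' @export
read_labeled_mask <- function(file) {
  v <- round(read_gray_image(file))
  known <- v %in% LABEL_CODES
  if (!all(known))
    stop("unknown label value(s) in ", file, ": ",
         paste(unique(v[!known]), collapse = ", "))
  out <- matrix(match(v, LABEL_CODES) - 1L, nrow(v), ncol(v))
  out
}

#' Write / read a probability map as 32-bit float TIFF
#'
#' Float storage is required: low-threshold mining uses probabilities down
#' to 1e-21, far below any integer sample resolution. The writer emits a
#' minimal single-strip little-endian TIFF with IEEE-float samples
#' (SampleFormat 3), since the tiff package writes integer samples only;
#' the reader is the tiff package, which does understand float samples.
#'
#' @param p numeric matrix in [0, 1].
#' @param file path to a `.tif` file.
#' @export
write_probability_map <- function(p, file) {
  h <- nrow(p); w <- ncol(p)
  con <- file(file, "wb")
  on.exit(close(con))
  data_offset <- 8L
  data_bytes <- 4L * h * w
  ifd_offset <- data_offset + data_bytes
  writeChar("II", con, nchars = 2, eos = NULL)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(ifd_offset, con, size = 4, endian = "little")
  writeBin(as.numeric(t(p)), con, size = 4, endian = "little")  # row-major
  entry <- function(tag, type, count, value) {
    writeBin(as.integer(tag), con, size = 2, endian = "little")
    writeBin(as.integer(type), con, size = 2, endian = "little")
    writeBin(as.integer(count), con, size = 4, endian = "little")
    if (type == 3L) {  # SHORT packs into the low bytes of the value field
      writeBin(as.integer(value), con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else {
      writeBin(as.integer(value), con, size = 4, endian = "little")
    }
  }
  writeBin(9L, con, size = 2, endian = "little")  # entry count
  entry(256L, 4L, 1L, w)            # ImageWidth
  entry(257L, 4L, 1L, h)            # ImageLength
  entry(258L, 3L, 1L, 32L)          # BitsPerSample
  entry(259L, 3L, 1L, 1L)           # Compression: none
  entry(262L, 3L, 1L, 1L)           # Photometric: BlackIsZero
  entry(273L, 4L, 1L, data_offset)  # StripOffsets
  entry(278L, 4L, 1L, h)            # RowsPerStrip
  entry(279L, 4L, 1L, data_bytes)   # StripByteCounts
  entry(339L, 3L, 1L, 3L)           # SampleFormat: IEEE float
  writeBin(0L, con, size = 4, endian = "little")  # no next IFD
  invisible(file)
}

#' @rdname write_probability_map
#' @export
read_probability_map <- function(file) {
  p <- tiff::readTIFF(file)
  if (length(dim(p)) == 3) p <- p[, , 1]
  p
}

#' Write / read YOLO-dialect box files
#'
#' One line per object: `class cx cy w h`, all normalized to [0, 1]; one
#' file per image with the same stem.
#'
#' @param records numeric vector `c(class, cx, cy, w, h)` or a matrix with
#'   those five columns (zero rows allowed).
#' @param file path to a `.txt` file.
#' @param image_size `c(height, width)` used to denormalize on read.
#' @return `read_yolo_boxes` returns a list of `vf_box` (empty for an
#'   empty file).
#' @export
write_yolo_boxes <- function(records, file) {
  if (is.null(records)) records <- matrix(numeric(0), 0, 5)
  if (is.null(dim(records))) records <- matrix(records, 1)
  lines <- apply(records, 1, function(r)
    paste(c(format(as.integer(r[1])), formatC(r[-1], format = "f", digits = 6)),
          collapse = " "))
  writeLines(lines, file)
  invisible(file)
}

#' @rdname write_yolo_boxes
#' @export
read_yolo_boxes <- function(file, image_size) {
  lines <- readLines(file)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(ln) {
    v <- as.numeric(strsplit(trimws(ln), "\\s+")[[1]])
    if (length(v) != 5) stop("malformed YOLO record in ", file)
    h <- image_size[1]; w <- image_size[2]
    cx <- v[2] * w; cy <- v[3] * h; bw <- v[4] * w; bh <- v[5] * h
    vf_box(cx - bw / 2, cy - bh / 2, cx + bw / 2, cy + bh / 2)
  })
}

#' Write / read a prompt bundle
#'
#' Serializes the prompts of one frame as JSON: image id, point list
#' (x, y, label, provenance), box corners (explicit null when absent),
#' and a configuration echo. Round-trippable.
#'
#' @param file path to a `.json` file.
#' @param image_id identifier of the frame.
#' @param points `point_prompt_set` data frame (or `NULL`).
#' @param box `vf_box` or `NULL`.
#' @param config list echoed verbatim (thresholds, iterations, seed, ...).
#' @return `read_prompts` returns a list with `image_id`, `points`,
#'   `box`, `config`.
#' @export
write_prompts <- function(file, image_id, points, box, config = list()) {
  payload <- list(
    image_id = image_id,
    points = if (is.null(points) || nrow(points) == 0) list() else
      lapply(seq_len(nrow(points)), function(i)
        list(x = points$x[i], y = points$y[i], label = points$label[i],
             provenance = points$provenance[i])),
    box = if (is.null(box)) NULL else as.list(unclass(box)),
    config = config)
  jsonlite::write_json(payload, file, auto_unbox = TRUE, null = "null",
                       digits = NA, pretty = TRUE)
  invisible(file)
}

#' @rdname write_prompts
#' @export
read_prompts <- function(file) {
  p <- jsonlite::read_json(file)
  pts <- if (length(p$points) == 0) NULL else {
    df <- do.call(rbind, lapply(p$points, function(q)
      data.frame(x = q$x, y = q$y, label = as.integer(q$label),
                 provenance = q$provenance)))
    class(df) <- c("point_prompt_set", class(df))
    df
  }
  box <- if (is.null(p$box)) NULL else
    vf_box(p$box$x_min, p$box$y_min, p$box$x_max, p$box$y_max)
  list(image_id = p$image_id, points = pts, box = box, config = p$config)
}

#' Write waveform and Dice CSV reports
#'
#' @param tab data frame from [waveform_table()].
#' @param file output CSV path.
#' @export
write_waveforms_csv <- function(tab, file) {
  utils::write.csv(tab[, c("frame", "missing", "side", "station",
                           "vfm_px", "vfw_px", "gaw_px2")],
                   file, row.names = FALSE)
  invisible(file)
}

#' Per-frame and mean Dice report
#'
#' Compares predicted against ground-truth labeled masks for the four
#' targets: the entire vocal-fold region (left+right), left fold, right
#' fold, and glottis.
#'
#' @param gt_labels,pred_labels lists of integer label matrices (0-3).
#' @param file optional CSV output path.
#' @return Data frame with `frame`, `vf`, `left`, `right`, `glottis`
#'   Dice values, plus a final row `frame = "mean"`.
#' @export
dice_report <- function(gt_labels, pred_labels, file = NULL) {
  stopifnot(length(gt_labels) == length(pred_labels))
  rows <- lapply(seq_along(gt_labels), function(k) {
    gt <- gt_labels[[k]]; pr <- pred_labels[[k]]
    data.frame(frame = as.character(k - 1),
               vf = dice(gt == 2L | gt == 3L, pr == 2L | pr == 3L),
               left = dice(gt == 2L, pr == 2L),
               right = dice(gt == 3L, pr == 3L),
               glottis = dice(gt == 1L, pr == 1L))
  })
  out <- do.call(rbind, rows)
  out <- rbind(out, data.frame(frame = "mean", vf = mean(out$vf),
                               left = mean(out$left), right = mean(out$right),
                               glottis = mean(out$glottis)))
  if (!is.null(file)) utils::write.csv(out, file, row.names = FALSE)
  out
}
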