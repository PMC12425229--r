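# Core data model: channel images, bounding boxes, per-cell annotations,
# frames and five-frame sequences.
#
# Conventions used throughout the package:
#   * images are numeric matrices indexed [row = y, col = x], 1-based in R;
#   * bounding boxes are 0-based, half-open pixel rectangles [x0,x1) x [y0,y1),
#     the convention of the external box tables, so a box covers matrix
#     elements [(y0+1):y1, (x0+1):x1];
#   * intensities are non-negative and stored unscaled (8- or 16-bit counts).

CELL_LABELS <- c("basal", "activated", "unidentified")
CHANNEL_NAMES <- c("green", "red", "transmitted")

#' Construct a channel image
#'
#' A single-channel fluorescence or transmitted-light image: a numeric matrix
#' of finite, non-negative intensities tagged with its channel name.
#'
#' @param pixels Numeric matrix, `[row = y, col = x]`, finite and `>= 0`.
#' @param channel One of `"green"`, `"red"`, `"transmitted"`.
#' @return A `channel_image` object (the matrix with a `channel` attribute).
#' @export
channel_image <- function(pixels, channel = c("green", "red", "transmitted")) {
  channel <- match.arg(channel)
  pixels <- as.matrix(pixels)
  if (!is.numeric(pixels) || nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop("'pixels' must be a numeric matrix with both dimensions >= 1")
  if (!all(is.finite(pixels)) || any(pixels < 0))
    stop("channel intensities must be finite and >= 0")
  structure(pixels, channel = channel, class = c("channel_image", "matrix"))
}

#' Construct a bounding box
#'
#' Boxes are 0-based, half-open pixel rectangles: `[x0, x1) x [y0, y1)`.
#'
#' @param x0,y0,x1,y1 Corner coordinates with `x0 < x1`, `y0 < y1`.
#' @return A named numeric vector of class `bbox`.
#' @export
bbox <- function(x0, y0, x1, y1) {
  b <- c(x0 = as.numeric(x0), y0 = as.numeric(y0),
         x1 = as.numeric(x1), y1 = as.numeric(y1))
  if (!all(is.finite(b))) stop("box coordinates must be finite")
  if (b["x0"] >= b["x1"] || b["y0"] >= b["y1"])
    stop("invalid box: need x0 < x1 and y0 < y1")
  structure(b, class = "bbox")
}

bbox_area <- function(b) unname((b[["x1"]] - b[["x0"]]) * (b[["y1"]] - b[["y0"]]))

bbox_center <- function(b) {
  c(x = (b[["x0"]] + b[["x1"]]) / 2, y = (b[["y0"]] + b[["y1"]]) / 2)
}

#' Tight bounding box of a binary mask
#'
#' @param mask Logical or 0/1 matrix with at least one foreground pixel.
#' @return A [bbox] in 0-based half-open coordinates.
#' @export
mask_bbox <- function(mask) {
  idx <- which(mask > 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("mask has no foreground pixels")
  bbox(x0 = min(idx[, 2L]) - 1L, y0 = min(idx[, 1L]) - 1L,
       x1 = max(idx[, 2L]), y1 = max(idx[, 1L]))
}

# rounding used by the YOLO dialect conversion: nearest, ties toward +Inf
round_half_up <- function(x) floor(x + 0.5)

#' Convert a normalized YOLO box to absolute pixel coordinates
#'
#' YOLO lines store `class cx cy w h` with all four geometry fields normalized
#' by image width/height. Conversion rounds to the nearest integer with ties
#' toward +Inf.
#'
#' @param cx,cy,w,h Normalized center and size in `[0, 1]`.
#' @param width,height Image size in pixels.
#' @return A [bbox].
#' @export
yolo_to_bbox <- function(cx, cy, w, h, width, height) {
  x0 <- round_half_up((cx - w / 2) * width)
  x1 <- round_half_up((cx + w / 2) * width)
  y0 <- round_half_up((cy - h / 2) * height)
  y1 <- round_half_up((cy + h / 2) * height)
  bbox(max(0, x0), max(0, y0), min(width, max(x0 + 1, x1)),
       min(height, max(y0 + 1, y1)))
}

#' Convert an absolute pixel box to the normalized YOLO dialect
#'
#' @param box A [bbox].
#' @param width,height Image size in pixels.
#' @return Numeric vector `c(cx, cy, w, h)`, normalized.
#' @export
bbox_to_yolo <- function(box, width, height) {
  c(cx = (box[["x0"]] + box[["x1"]]) / 2 / width,
    cy = (box[["y0"]] + box[["y1"]]) / 2 / height,
    w  = (box[["x1"]] - box[["x0"]]) / width,
    h  = (box[["y1"]] - box[["y0"]]) / height)
}

#' Construct a per-cell annotation record
#'
#' @param cell_id Integer identifier, unique within a frame.
#' @param mask Logical matrix (full frame size) with >= 1 foreground pixel.
#' @param box A [bbox]; defaults to the tight box of `mask`.
#' @param label One of `"basal"`, `"activated"`, `"unidentified"`.
#' @return A `cell_record` object.
#' @export
cell_record <- function(cell_id, mask, box = NULL, label) {
  if (!label %in% CELL_LABELS)
    stop(sprintf("invalid label '%s' for cell %s: must be one of %s",
                 label, cell_id, paste(CELL_LABELS, collapse = ", ")))
  mask <- mask > 0
  if (!any(mask)) stop(sprintf("cell %s: mask has no foreground pixels", cell_id))
  if (is.null(box)) box <- mask_bbox(mask)
  structure(list(cell_id = as.integer(cell_id), mask = mask, box = box,
                 label = label),
            class = "cell_record")
}

#' Construct an annotated frame
#'
#' One time point of a sequence: the three channel images plus the per-cell
#' annotation records.
#'
#' @param timepoint Integer in `0..4`.
#' @param channels Named list with elements `green`, `red`, `transmitted`,
#'   all matrices of one shape (plain matrices are accepted and wrapped).
#' @param cells List of [cell_record] objects with unique `cell_id`s.
#' @return An `annotated_frame` object; cells are ordered by `cell_id`.
#' @export
annotated_frame <- function(timepoint, channels, cells = list()) {
  timepoint <- as.integer(timepoint)
  if (timepoint < 0L || timepoint > 4L) stop("timepoint must be in 0..4")
  if (!all(CHANNEL_NAMES %in% names(channels)))
    stop("channels must be a named list with green, red and transmitted")
  channels <- lapply(CHANNEL_NAMES, function(ch) {
    img <- channels[[ch]]
    if (inherits(img, "channel_image")) img else channel_image(img, ch)
  })
  names(channels) <- CHANNEL_NAMES
  dims <- unique(lapply(channels, dim))
  if (length(dims) != 1L) stop("all channels must share one image shape")
  ids <- vapply(cells, function(cl) cl$cell_id, integer(1))
  if (anyDuplicated(ids)) stop("cell_ids must be unique within a frame")
  for (cl in cells) {
    if (!identical(dim(cl$mask), dims[[1L]]))
      stop(sprintf("cell %d: mask shape differs from frame shape", cl$cell_id))
  }
  cells <- cells[order(ids)]
  structure(list(timepoint = timepoint, channels = channels, cells = cells),
            class = "annotated_frame")
}

frame_dim <- function(frame) dim(frame$channels$green)

#' Construct a five-frame sequence
#'
#' The unit the tracker and the transition summaries consume: exactly five
#' [annotated_frame]s at timepoints 0..4 under one feeding condition.
#'
#' @param frames List of five [annotated_frame]s ordered by timepoint.
#' @param condition `"fed"` or `"starved"`.
#' @param replicate_id Identifier used for within-replicate normalization.
#' @return A `cell_sequence` object.
#' @export
cell_sequence <- function(frames, condition = c("fed", "starved"),
                          replicate_id = "r1") {
  condition <- match.arg(condition)
  if (length(frames) != 5L) stop("a sequence has exactly five frames")
  tps <- vapply(frames, function(f) f$timepoint, integer(1))
  if (!identical(tps, 0:4)) stop("frame timepoints must be 0,1,2,3,4 in order")
  dims <- unique(lapply(frames, frame_dim))
  if (length(dims) != 1L) stop("all frames must share one image shape")
  structure(list(frames = frames, condition = condition,
                 replicate_id = as.character(replicate_id)),
            class = "cell_sequence")
}

#' @export
print.annotated_frame <- function(x, ...) {
  d <- frame_dim(x)
  labs <- table(factor(vapply(x$cells, `[[`, "", "label"), CELL_LABELS))
  cat(sprintf("annotated_frame: t=%d, %dx%d px, %d cells (%s)\n",
              x$timepoint, d[1L], d[2L], length(x$cells),
              paste(names(labs), labs, sep = "=", collapse = ", ")))
  invisible(x)
}

#' @export
print.cell_sequence <- function(x, ...) {
  n <- vapply(x$frames, function(f) length(f$cells), integer(1))
  cat(sprintf("cell_sequence: condition=%s, replicate=%s, cells/frame: %s\n",
              x$condition, x$replicate_id, paste(n, collapse = " ")))
  invisible(x)
}

#' Construct a detection
#'
#' A candidate cell produced by any detector (the reference classical detector
#' or an external model's output).
#'
#' @param box A [bbox].
#' @param confidence Real in `[0, 1]`.
#' @param mask Optional logical matrix (full frame size).
#' @return A `detection` object.
#' @export
detection <- function(box, confidence, mask = NULL) {
  if (!is.finite(confidence) || confidence < 0 || confidence > 1)
    stop("confidence must be in [0, 1]")
  if (!inherits(box, "bbox")) box <- bbox(box[[1]], box[[2]], box[[3]], box[[4]])
  structure(list(box = box, confidence = as.numeric(confidence),
                 mask = if (!is.null(mask)) mask > 0),
            class = "detection")
}
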