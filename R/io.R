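# Readers and writers for annotated time-lapse data: per-channel TIFFs,
# per-cell binary masks, box tables (CSV absolute and YOLO normalized
# dialects), label tables, and train/validation/test split lists.

#' Read a single-channel TIFF as raw intensity counts
#'
#' Accepts 8- and 16-bit files; intensities are returned unscaled (0..255 or
#' 0..65535) as a numeric matrix.
#'
#' @param path TIFF file path.
#' @param channel Channel tag for the returned [channel_image].
#' @return A [channel_image].
#' @export
read_channel_tiff <- function(path, channel = "green") {
  if (!file.exists(path)) stop(sprintf("missing channel file: %s", path))
  px <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(px)) == 3L) {
    if (dim(px)[3L] != 1L)
      stop(sprintf("%s: expected a single-channel TIFF", path))
    px <- px[, , 1L]
  }
  channel_image(px, channel)
}

#' Write a channel image as a single-channel TIFF
#'
#' Intensities are written at 16-bit depth (8-bit if `bits = 8`); values must
#' be integers representable at that depth so that read/write round-trips
#' bit-exactly.
#'
#' @param img Matrix or [channel_image] of integer-valued intensities.
#' @param path Output file path.
#' @param bits 8 or 16.
#' @export
write_channel_tiff <- function(img, path, bits = 16L) {
  maxv <- 2^bits - 1
  m <- unclass(img)
  attr(m, "channel") <- NULL
  if (any(m < 0) || any(m > maxv) || any(m != round(m)))
    stop(sprintf("intensities must be integers in 0..%d for %d-bit TIFF",
                 maxv, bits))
  tiff::writeTIFF(m / maxv, path, bits.per.sample = as.integer(bits))
  invisible(path)
}

read_mask_file <- function(path) {
  m <- if (grepl("\\.png$", path, ignore.case = TRUE)) {
    px <- png::readPNG(path)
    if (length(dim(px)) == 3L) px <- px[, , 1L]
    px
  } else {
    px <- tiff::readTIFF(path, as.is = TRUE)
    if (length(dim(px)) == 3L) px <- px[, , 1L]
    px
  }
  m > 0
}

#' Read one annotated frame from disk
#'
#' @param channel_paths Named character vector/list with elements `green`,
#'   `red`, `transmitted`: the three single-channel TIFF paths.
#' @param mask_dir Directory containing one binary mask file per cell, named
#'   `*cell<ID>*.png` (or `.tif`).
#' @param boxes_path Box table: either a CSV with columns
#'   `cell_id,x0,y0,x1,y1` (0-based half-open) or a YOLO `.txt` file with one
#'   `class cx cy w h` line per cell (normalized; lines map to masks in
#'   ascending `cell_id` order).
#' @param labels_path CSV with columns `cell_id,label`.
#' @param timepoint Timepoint (0..4) recorded on the frame.
#' @return An [annotated_frame]. If a stored box is not the tight bounding box
#'   of its mask it is kept as stored and a warning is recorded (annotation
#'   inconsistencies are tolerated, not repaired).
#' @export
read_annotated_frame <- function(channel_paths, mask_dir, boxes_path,
                                 labels_path, timepoint = 0L) {
  channel_paths <- as.list(channel_paths)
  channels <- lapply(CHANNEL_NAMES, function(ch) {
    p <- channel_paths[[ch]]
    if (is.null(p)) stop(sprintf("missing channel path: %s", ch))
    read_channel_tiff(p, ch)
  })
  names(channels) <- CHANNEL_NAMES
  d <- dim(channels$green)

  mask_files <- list.files(mask_dir, pattern = "cell[0-9]+.*\\.(png|tif|tiff)$",
                           full.names = TRUE, ignore.case = TRUE)
  ids <- as.integer(sub(".*cell([0-9]+).*", "\\1", basename(mask_files)))
  ord <- order(ids)
  mask_files <- mask_files[ord]; ids <- ids[ord]
  if (anyDuplicated(ids))
    stop(sprintf("duplicate mask file for cell %d", ids[duplicated(ids)][1L]))

  labels_df <- if (file.size(labels_path) > 0)
    utils::read.csv(labels_path, stringsAsFactors = FALSE)
  else data.frame(cell_id = integer(), label = character())
  bad <- setdiff(labels_df$label, CELL_LABELS)
  if (length(bad))
    stop(sprintf("invalid label '%s' (must be one of %s)",
                 bad[1L], paste(CELL_LABELS, collapse = ", ")))

  boxes <- read_box_table(boxes_path, width = d[2L], height = d[1L], ids = ids)

  for (id in ids) {
    if (!id %in% labels_df$cell_id)
      stop(sprintf("cell %d has a mask but no label", id))
    if (!id %in% boxes$cell_id)
      stop(sprintf("cell %d has a mask but no bounding box", id))
  }
  extra <- setdiff(union(labels_df$cell_id, boxes$cell_id), ids)
  if (length(extra))
    stop(sprintf("cell %d has annotations but no mask file", extra[1L]))

  cells <- lapply(seq_along(ids), function(i) {
    id <- ids[i]
    mask <- read_mask_file(mask_files[i])
    if (!identical(dim(mask), d))
      stop(sprintf("cell %d: mask shape differs from channel shape", id))
    b <- boxes[boxes$cell_id == id, ]
    box <- bbox(b$x0, b$y0, b$x1, b$y1)
    tight <- mask_bbox(mask)
    if (!isTRUE(all.equal(unclass(box), unclass(tight))))
      warning(sprintf("cell %d: stored box is not the tight box of its mask",
                      id), call. = FALSE)
    if (!mask_in_bbox(mask, box))
      box <- bbox(min(box[["x0"]], tight[["x0"]]), min(box[["y0"]], tight[["y0"]]),
                  max(box[["x1"]], tight[["x1"]]), max(box[["y1"]], tight[["y1"]]))
    cell_record(id, mask, box, labels_df$label[labels_df$cell_id == id])
  })
  annotated_frame(timepoint, channels, cells)
}

mask_in_bbox <- function(mask, box) {
  tight <- mask_bbox(mask)
  tight[["x0"]] >= box[["x0"]] && tight[["y0"]] >= box[["y0"]] &&
    tight[["x1"]] <= box[["x1"]] && tight[["y1"]] <= box[["y1"]]
}

read_box_table <- function(path, width, height, ids) {
  if (grepl("\\.txt$", path, ignore.case = TRUE)) {
    lines <- if (file.size(path) > 0) readLines(path) else character()
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) != length(ids))
      stop(sprintf("YOLO box file has %d lines but there are %d masks",
                   length(lines), length(ids)))
    rows <- lapply(seq_along(lines), function(i) {
      f <- as.numeric(strsplit(trimws(lines[i]), "[[:space:]]+")[[1L]])
      if (length(f) != 5L) stop(sprintf("malformed YOLO line %d", i))
      b <- yolo_to_bbox(f[2L], f[3L], f[4L], f[5L], width, height)
      data.frame(cell_id = ids[i], x0 = b[["x0"]], y0 = b[["y0"]],
                 x1 = b[["x1"]], y1 = b[["y1"]])
    })
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  } else {
    if (file.size(path) == 0)
      return(data.frame(cell_id = integer(), x0 = numeric(), y0 = numeric(),
                        x1 = numeric(), y1 = numeric()))
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
}

#' Write one annotated frame to disk
#'
#' Emits, under `out_dir`: the three channel TIFFs (`<prefix>_<channel>.tif`),
#' one binary mask PNG per cell (`masks/<prefix>_cell<ID>_mask.png`), a box
#' CSV (`<prefix>_boxes.csv`), a YOLO-dialect box file (`<prefix>_boxes.txt`),
#' and a labels CSV (`<prefix>_labels.csv`). [read_annotated_frame] on the
#' output reproduces the frame exactly.
#'
#' @param frame An [annotated_frame] with integer-valued intensities.
#' @param out_dir Output directory (created if needed).
#' @param prefix Filename prefix; defaults to `t<timepoint>`.
#' @param combined_labels Also write a combined label image
#'   (`<prefix>_labelimage.tif`, pixel value = cell_id)?
#' @return Invisibly, the named list of written paths.
#' @export
write_annotated_frame <- function(frame, out_dir,
                                  prefix = sprintf("t%d", frame$timepoint),
                                  combined_labels = FALSE) {
  dir.create(file.path(out_dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop(sprintf("cannot create directory %s", out_dir))
  d <- frame_dim(frame)
  paths <- list()
  for (ch in CHANNEL_NAMES) {
    p <- file.path(out_dir, sprintf("%s_%s.tif", prefix, ch))
    write_channel_tiff(frame$channels[[ch]], p)
    paths[[ch]] <- p
  }
  boxes <- data.frame(cell_id = integer(), x0 = numeric(), y0 = numeric(),
                      x1 = numeric(), y1 = numeric())
  labels <- data.frame(cell_id = integer(), label = character())
  yolo <- character()
  class_idx <- stats::setNames(seq_along(CELL_LABELS) - 1L, CELL_LABELS)
  for (cl in frame$cells) {
    mp <- file.path(out_dir, "masks",
                    sprintf("%s_cell%04d_mask.png", prefix, cl$cell_id))
    png::writePNG(matrix(as.numeric(cl$mask), nrow(cl$mask)), mp)
    boxes <- rbind(boxes, data.frame(cell_id = cl$cell_id,
                                     x0 = cl$box[["x0"]], y0 = cl$box[["y0"]],
                                     x1 = cl$box[["x1"]], y1 = cl$box[["y1"]]))
    labels <- rbind(labels, data.frame(cell_id = cl$cell_id, label = cl$label))
    yl <- bbox_to_yolo(cl$box, d[2L], d[1L])
    yolo <- c(yolo, sprintf("%d %.8f %.8f %.8f %.8f", class_idx[[cl$label]],
                            yl[["cx"]], yl[["cy"]], yl[["w"]], yl[["h"]]))
  }
  paths$boxes <- file.path(out_dir, sprintf("%s_boxes.csv", prefix))
  utils::write.csv(boxes, paths$boxes, row.names = FALSE)
  paths$yolo <- file.path(out_dir, sprintf("%s_boxes.txt", prefix))
  writeLines(yolo, paths$yolo)
  paths$labels <- file.path(out_dir, sprintf("%s_labels.csv", prefix))
  utils::write.csv(labels, paths$labels, row.names = FALSE)
  paths$mask_dir <- file.path(out_dir, "masks")
  if (combined_labels) {
    li <- matrix(0L, d[1L], d[2L])
    for (cl in frame$cells) li[cl$mask] <- cl$cell_id
    paths$label_image <- file.path(out_dir, sprintf("%s_labelimage.tif", prefix))
    write_channel_tiff(li, paths$label_image)
  }
  invisible(paths)
}

#' Write a whole sequence to disk
#'
#' One subdirectory per frame (`frame0` .. `frame4`) written with
#' [write_annotated_frame], plus `sequence.json` recording condition and
#' replicate.
#'
#' @param seq A [cell_sequence].
#' @param out_dir Output directory.
#' @return Invisibly, `out_dir`.
#' @export
write_sequence <- function(seq, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (f in seq$frames)
    write_annotated_frame(f, file.path(out_dir, sprintf("frame%d", f$timepoint)))
  jsonlite::write_json(list(condition = seq$condition,
                            replicate_id = seq$replicate_id),
                       file.path(out_dir, "sequence.json"), auto_unbox = TRUE)
  invisible(out_dir)
}

#' Load a train/validation/test split list
#'
#' The list file assigns each filename to one partition:
#' `filename<TAB>partition`, with partition one of `train`, `validation`,
#' `test`.
#'
#' @param list_path Path to the split list.
#' @return Named list of three disjoint character vectors (`train`,
#'   `validation`, `test`) covering every listed filename exactly once.
#' @export
load_split_list <- function(list_path) {
  if (!file.exists(list_path)) stop(sprintf("missing split list: %s", list_path))
  lines <- readLines(list_path)
  lines <- lines[nzchar(trimws(lines))]
  out <- list(train = character(), validation = character(), test = character())
  seen <- character()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(f) != 2L) stop(sprintf("malformed split line: '%s'", ln))
    fname <- trimws(f[1L]); part <- trimws(f[2L])
    if (!part %in% names(out))
      stop(sprintf("unknown partition tag '%s' for %s", part, fname))
    if (fname %in% seen)
      stop(sprintf("filename '%s' assigned to more than one partition", fname))
    seen <- c(seen, fname)
    out[[part]] <- c(out[[part]], fname)
  }
  out
}
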