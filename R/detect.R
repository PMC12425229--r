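# Reference classical detector and the detection/segmentation metrology:
# box IoU, greedy confidence-ordered matching, COCO-style average precision
# (101-point interpolation), and pixel-level confusion-matrix metrics.

#' Intersection over union of two bounding boxes
#'
#' Areas are computed on the half-open pixel convention, so `[0,0,2,1)` has
#' area 2.
#'
#' @param a,b [bbox] objects.
#' @return IoU in `[0, 1]`.
#' @export
box_iou <- function(a, b) {
  ix <- max(0, min(a[["x1"]], b[["x1"]]) - max(a[["x0"]], b[["x0"]]))
  iy <- max(0, min(a[["y1"]], b[["y1"]]) - max(a[["y0"]], b[["y0"]]))
  inter <- ix * iy
  union <- bbox_area(a) + bbox_area(b) - inter
  if (union <= 0) return(0)
  inter / union
}

#' Match detections to ground-truth boxes
#'
#' Standard average-precision matching: detections are processed in
#' descending confidence (ties broken by lower index) and each is matched to
#' the still-unmatched ground truth of maximal IoU, provided that IoU reaches
#' `iou_thresh`; otherwise it is left unmatched (a false positive).
#'
#' @param dets List of [detection]s.
#' @param gts List of ground-truth [bbox]es.
#' @param iou_thresh Matching threshold in `(0, 1]`.
#' @return A `detection_match` list: `pairs` (data frame of `det`, `gt`,
#'   `iou`; 1-based indices), `unmatched_dets`, `unmatched_gts`.
#' @export
match_detections <- function(dets, gts, iou_thresh = 0.5) {
  stopifnot(iou_thresh > 0, iou_thresh <= 1)
  nd <- length(dets); ng <- length(gts)
  conf <- vapply(dets, `[[`, numeric(1), "confidence")
  ord <- order(-conf, seq_len(nd))
  gt_taken <- rep(FALSE, ng)
  pairs <- data.frame(det = integer(), gt = integer(), iou = numeric())
  for (di in ord) {
    if (ng == 0L) break
    ious <- vapply(seq_len(ng), function(gi)
      if (gt_taken[gi]) -1 else box_iou(dets[[di]]$box, gts[[gi]]), numeric(1))
    gi <- which.max(ious)
    if (length(gi) && ious[gi] >= iou_thresh) {
      gt_taken[gi] <- TRUE
      pairs <- rbind(pairs, data.frame(det = di, gt = gi, iou = ious[gi]))
    }
  }
  structure(list(pairs = pairs[order(pairs$det), , drop = FALSE],
                 unmatched_dets = setdiff(seq_len(nd), pairs$det),
                 unmatched_gts = which(!gt_taken)),
            class = "detection_match")
}

#' Average precision over a set of images
#'
#' Detections are pooled across images, sorted by descending confidence, and
#' matched per image with [match_detections] semantics. AP uses COCO-style
#' 101-point interpolation: precision is evaluated at recalls 0, 0.01, ...,
#' 1.00 after taking the precision envelope (maximum precision at recall
#' `>= r`).
#'
#' @param dets List (one element per image) of lists of [detection]s.
#' @param gts List (same length) of lists of ground-truth [bbox]es.
#' @param iou_thresh IoU threshold.
#' @return AP in `[0, 1]`. It is an error if there are zero ground truths.
#' @export
average_precision <- function(dets, gts, iou_thresh = 0.5) {
  stopifnot(length(dets) == length(gts))
  n_gt <- sum(lengths(gts))
  if (n_gt == 0L) stop("average precision is undefined with zero ground truths")
  # per-image greedy matching in global confidence order
  flat <- do.call(rbind, lapply(seq_along(dets), function(img) {
    if (length(dets[[img]]) == 0L) return(NULL)
    data.frame(img = img, idx = seq_along(dets[[img]]),
               conf = vapply(dets[[img]], `[[`, numeric(1), "confidence"))
  }))
  if (is.null(flat) || nrow(flat) == 0L) return(0)
  flat <- flat[order(-flat$conf, flat$img, flat$idx), ]
  taken <- lapply(gts, function(g) rep(FALSE, length(g)))
  tp <- logical(nrow(flat))
  for (k in seq_len(nrow(flat))) {
    img <- flat$img[k]
    g <- gts[[img]]
    if (length(g) == 0L) next
    box <- dets[[img]][[flat$idx[k]]]$box
    ious <- vapply(seq_along(g), function(gi)
      if (taken[[img]][gi]) -1 else box_iou(box, g[[gi]]), numeric(1))
    gi <- which.max(ious)
    if (length(gi) && ious[gi] >= iou_thresh) {
      taken[[img]][gi] <- TRUE
      tp[k] <- TRUE
    }
  }
  cum_tp <- cumsum(tp)
  precision <- cum_tp / seq_along(tp)
  recall <- cum_tp / n_gt
  recall_grid <- seq(0, 1, by = 0.01)
  interp <- vapply(recall_grid, function(r) {
    ok <- recall >= r - 1e-12
    if (!any(ok)) 0 else max(precision[ok])
  }, numeric(1))
  mean(interp)
}

#' Mean average precision over an IoU threshold range
#'
#' `mAP50-95` is the mean of [average_precision] at thresholds 0.50, 0.55,
#' ..., 0.95; a single threshold gives `mAP50`.
#'
#' @inheritParams average_precision
#' @param thresholds IoU thresholds to average over.
#' @return Mean AP.
#' @export
mean_average_precision <- function(dets, gts,
                                   thresholds = seq(0.5, 0.95, by = 0.05)) {
  mean(vapply(thresholds, function(th) average_precision(dets, gts, th),
              numeric(1)))
}

#' Pixel-level segmentation metrics
#'
#' Foreground confusion-matrix metrics between a predicted and a true binary
#' mask: IoU, F1 (Dice), precision, recall, and all-pixel accuracy. When both
#' masks are empty all metrics are 1 (the masks agree there is nothing); an
#' empty truth with a nonempty prediction gives IoU, precision and F1 of 0
#' (recall is 1: there were no positives to find).
#'
#' @param pred,truth Binary matrices of one shape.
#' @return Named list: `iou`, `f1`, `precision`, `recall`, `accuracy`.
#' @export
pixel_metrics <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth)))
    stop("pred and truth must have the same shape")
  p <- pred > 0; t <- truth > 0
  tp <- sum(p & t); fp <- sum(p & !t); fn <- sum(!p & t); tn <- sum(!p & !t)
  iou <- if (tp + fp + fn == 0) 1 else tp / (tp + fp + fn)
  precision <- if (tp + fp == 0) { if (fn == 0) 1 else 0 } else tp / (tp + fp)
  recall <- if (tp + fn == 0) 1 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  list(iou = iou, f1 = f1, precision = precision, recall = recall,
       accuracy = (tp + tn) / length(p))
}

#' Parameters for the classical reference detector
#'
#' @param sigma Gaussian smoothing SD (px).
#' @param min_area Minimum component area kept (px).
#' @param watershed_tolerance Minimum distance-map height (px) separating two
#'   seeds for the watershed split of touching components; about half a cell
#'   radius splits genuinely touching cells without shattering single blobs.
#' @return A parameter list.
#' @export
detect_params <- function(sigma = 2, min_area = 50, watershed_tolerance = 5) {
  list(sigma = sigma, min_area = min_area,
       watershed_tolerance = watershed_tolerance)
}

#' Classical reference detector
#'
#' Fluorescence-sum segmentation: green + red channels are summed, Gaussian
#' smoothed, thresholded by Otsu's method, connected components below
#' `min_area` are dropped, and touching components are split by a
#' distance-transform watershed. Confidence is each component's mean smoothed
#' intensity normalized by the maximum component mean (so the brightest
#' component has confidence 1). Parameters are tuned for the synthetic
#' generator's default configuration, not for real microscopy.
#'
#' @param frame An [annotated_frame], or `NULL` if `channels` is given.
#' @param channels Optional named list with `green` and `red` matrices.
#' @param params A [detect_params] list.
#' @return List of [detection]s, each with a tight box and a component mask;
#'   empty on a blank image.
#' @export
reference_detect <- function(frame = NULL, channels = NULL,
                             params = detect_params()) {
  if (is.null(channels)) channels <- frame$channels
  img <- (unclass(channels$green) + unclass(channels$red)) / (2 * 65535)
  sm <- EBImage::gblur(img, sigma = params$sigma)
  # Otsu on log intensities: fluorescence spans decades (background, cytosol,
  # puncta), and on the raw scale the threshold lands between cytosol and
  # puncta instead of between background and cells
  lg <- log10(sm + 1e-4)
  rng <- range(lg)
  if (diff(rng) < 1e-9) return(list())
  th <- EBImage::otsu(EBImage::Image(lg), range = rng)
  bin <- lg > th
  if (!any(bin)) return(list())
  # smoothing the distance map suppresses spurious maxima from boundary
  # wiggles before the watershed split of touching cells
  dm <- as.matrix(EBImage::imageData(EBImage::distmap(bin * 1)))
  dm <- EBImage::gblur(dm, sigma = params$sigma)
  dm[!bin] <- 0
  lbl <- EBImage::watershed(EBImage::Image(dm),
                            tolerance = params$watershed_tolerance, ext = 1)
  lbl <- as.matrix(EBImage::imageData(lbl))
  bg_level <- mean(sm[!bin])
  dets <- list()
  for (k in seq_len(max(lbl))) {
    comp <- lbl == k
    if (sum(comp) < params$min_area) next
    # confidence: component contrast over background; dim, noise-level
    # components score low and fall to the confidence filter
    conf <- max(0, 1 - bg_level / mean(sm[comp]))
    dets[[length(dets) + 1L]] <-
      detection(mask_bbox(comp), confidence = conf, mask = comp)
  }
  dets
}

#' Crop the padded box region out of channel images
#'
#' @param channels Named list of channel matrices (or an [annotated_frame]'s
#'   `channels` element), or a single matrix.
#' @param box A [bbox] lying within the frame.
#' @param pad Padding in pixels, clipped at the image border.
#' @return Cropped channels (same structure as the input); the crop carries a
#'   `crop_box` attribute with the realized (possibly clipped) box.
#' @export
crop_cell <- function(channels, box, pad = 0) {
  single <- is.matrix(channels)
  chs <- if (single) list(img = channels) else channels
  d <- dim(chs[[1L]])
  if (box[["x0"]] < 0 || box[["y0"]] < 0 || box[["x1"]] > d[2L] ||
      box[["y1"]] > d[1L])
    stop("box lies outside the frame")
  x0 <- max(0, box[["x0"]] - pad); y0 <- max(0, box[["y0"]] - pad)
  x1 <- min(d[2L], box[["x1"]] + pad); y1 <- min(d[1L], box[["y1"]] + pad)
  out <- lapply(chs, function(m) unclass(m)[(y0 + 1):y1, (x0 + 1):x1,
                                            drop = FALSE])
  res <- if (single) out$img else out
  attr(res, "crop_box") <- bbox(x0, y0, x1, y1)
  res
}

#' Zero all pixels outside a mask
#'
#' Isolates a cell against a black background, the input convention of the
#' downstream classifier stages.
#'
#' @param channels Cropped channel list (or a single matrix).
#' @param mask Binary matrix of the same shape as each channel.
#' @return Masked channels, same structure as the input.
#' @export
apply_mask <- function(channels, mask) {
  single <- is.matrix(channels) && !is.list(channels)
  chs <- if (single) list(img = channels) else channels
  if (!identical(dim(chs[[1L]]), dim(mask)))
    stop("mask shape must match the channel shape")
  out <- lapply(chs, function(m) { m <- unclass(m); m[!(mask > 0)] <- 0; m })
  if (single) out$img else out
}

#' Filter detections by confidence
#'
#' Keeps detections with confidence at or above the threshold, preserving
#' order. The default 0.65 is the operating point used for cell counting.
#'
#' @param dets List of [detection]s.
#' @param threshold Confidence threshold in `[0, 1]`.
#' @return The retained detections.
#' @export
filter_by_confidence <- function(dets, threshold = 0.65) {
  stopifnot(threshold >= 0, threshold <= 1)
  dets[vapply(dets, function(d) d$confidence >= threshold, logical(1))]
}
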