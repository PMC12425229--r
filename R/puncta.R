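# Red-channel punctum (RFP spot) quantification and the threshold-based
# autophagy classifier: top-hat spot segmentation inside each cell mask,
# within-replicate normalization with log10 transform, the 95th-percentile
# activation threshold, cell morphology (area, Crofton perimeter,
# circularity), class contrasts, and confusion-matrix metrics including the
# multiclass Matthews correlation coefficient.

#' Parameters for red-channel spot segmentation
#'
#' @param tophat_radius Radius (px) of the white-top-hat structuring disc;
#'   must exceed the largest expected punctum radius.
#' @param mad_k Robust threshold factor: spots are pixels above
#'   `median + mad_k * MAD` of the top-hat response inside the cell mask.
#' @param min_spot_area Minimum surviving component area (px).
#' @return A parameter list.
#' @export
spot_params <- function(tophat_radius = 7, mad_k = 3, min_spot_area = 4) {
  list(tophat_radius = tophat_radius, mad_k = mad_k,
       min_spot_area = min_spot_area)
}

#' Segment red-channel puncta within one cell
#'
#' White-top-hat background removal (disc of `tophat_radius`), then a robust
#' per-cell threshold (median + `mad_k` * MAD of the top-hat response over
#' the mask), connected components, and a minimum-area filter. Cells with no
#' surviving spot return `spot_count = 0` and are flagged `no_spots`; such
#' cells are excluded from threshold classification downstream.
#'
#' @param red Red [channel_image] (or matrix) of the full frame.
#' @param cell_mask Binary matrix, same shape, with >= 1 foreground pixel.
#' @param params A [spot_params] list.
#' @param cell_id Identifier copied into the record.
#' @return A `spot_record` list: `cell_id`, `spot_areas`, `spot_count`,
#'   `total_area`, `max_area`, `no_spots`.
#' @export
segment_spots <- function(red, cell_mask, params = spot_params(),
                          cell_id = NA_integer_) {
  mask <- cell_mask > 0
  if (!any(mask)) stop("empty cell mask")
  img <- unclass(red) / 65535
  # work on the padded box window; pixels outside the cell are filled with
  # the cell's median so the top-hat sees no artificial step at the boundary
  bb <- mask_bbox(mask)
  pad <- ceiling(params$tophat_radius) + 1L
  d <- dim(mask)
  y0 <- max(1L, bb[["y0"]] + 1L - pad); y1 <- min(d[1L], bb[["y1"]] + pad)
  x0 <- max(1L, bb[["x0"]] + 1L - pad); x1 <- min(d[2L], bb[["x1"]] + pad)
  win <- img[y0:y1, x0:x1]
  mwin <- mask[y0:y1, x0:x1]
  win[!mwin] <- stats::median(win[mwin])
  brush <- EBImage::makeBrush(2L * ceiling(params$tophat_radius) + 1L, "disc")
  th <- as.matrix(EBImage::imageData(EBImage::whiteTopHat(win, brush)))
  mask <- mwin
  vals <- th[mask]
  cut <- stats::median(vals) + params$mad_k * stats::mad(vals)
  bin <- th > cut & mask
  areas <- integer()
  if (any(bin)) {
    lbl <- EBImage::bwlabel(bin * 1)
    tab <- tabulate(as.integer(lbl[lbl > 0]))
    areas <- tab[tab >= params$min_spot_area]
  }
  areas <- sort(as.numeric(areas), decreasing = TRUE)
  structure(list(cell_id = cell_id, spot_areas = areas,
                 spot_count = length(areas), total_area = sum(areas),
                 max_area = if (length(areas)) max(areas) else 0,
                 no_spots = length(areas) == 0L),
            class = "spot_record")
}

#' Within-replicate normalization followed by log10
#'
#' Each value is divided by the median of its replicate and then log10
#' transformed, making features comparable across experimental replicates and
#' approximately normal. All values must be strictly positive: cells with no
#' segmented spots are excluded upstream, not imputed.
#'
#' @param values Positive feature values.
#' @param replicate_ids Replicate identifier per value.
#' @return Transformed values, same order.
#' @export
normalize_and_log <- function(values, replicate_ids) {
  if (length(values) != length(replicate_ids))
    stop("values and replicate_ids must have equal length")
  if (any(!is.finite(values)) || any(values <= 0))
    stop("all values must be finite and > 0 (exclude no-spot cells first)")
  out <- numeric(length(values))
  for (r in unique(replicate_ids)) {
    sel <- replicate_ids == r
    m <- stats::median(values[sel])
    if (m == 0) stop(sprintf("replicate '%s' has an all-zero median", r))
    out[sel] <- log10(values[sel] / m)
  }
  out
}

#' Percentile-based activation threshold
#'
#' The activation cut is a high percentile (default the 95th) of the
#' calibration population: transformed spot-area values of fed cells at the
#' calibration timepoint. Uses the continuous linear-interpolation percentile
#' (order-statistic index `h = (n - 1) p / 100`, type 7).
#'
#' @param values Calibration feature values (>= 2 of them).
#' @param percentile Percentile in `(0, 100)`.
#' @return The threshold.
#' @export
activation_threshold <- function(values, percentile = 95) {
  if (length(values) < 2L) stop("need at least 2 calibration values")
  stopifnot(percentile > 0, percentile < 100)
  unname(stats::quantile(values, percentile / 100, type = 7, names = FALSE))
}

#' Classify cells by the activation threshold
#'
#' Cells whose spot-area feature exceeds the threshold are called
#' `activated`, the rest `basal`. Cells flagged `no_spots` are excluded from
#' classification and reported via the `excluded` attribute.
#'
#' @param records Data frame with columns `cell_id`, `feature` (the
#'   transformed spot-area feature) and optionally `no_spots`.
#' @param threshold The activation threshold (finite).
#' @return Data frame `cell_id`, `label` for classified cells, with excluded
#'   `cell_id`s in `attr(, "excluded")`.
#' @export
classify_by_threshold <- function(records, threshold) {
  stopifnot(is.finite(threshold))
  no_spots <- if ("no_spots" %in% names(records)) records$no_spots
              else rep(FALSE, nrow(records))
  keep <- records[!no_spots, , drop = FALSE]
  out <- data.frame(cell_id = keep$cell_id,
                    label = ifelse(keep$feature > threshold,
                                   "activated", "basal"))
  attr(out, "excluded") <- records$cell_id[no_spots]
  out
}

# Crofton 4-direction perimeter: pad the mask, code each 2x2 neighbourhood
# configuration (weights 1,4,2,8), and sum the per-configuration intercept
# coefficients.
crofton_perimeter <- function(mask) {
  m <- (mask > 0) * 1L
  p <- matrix(0L, nrow(m) + 2L, ncol(m) + 2L)
  p[2:(nrow(m) + 1L), 2:(ncol(m) + 1L)] <- m
  nr <- nrow(p); nc <- ncol(p)
  # 2x2 window configuration code: top-left 8, top-right 2, bottom-left 4,
  # bottom-right 1 (the bit convention the coefficient table is defined for)
  a <- p[1:(nr - 1L), 1:(nc - 1L)]
  b <- p[1:(nr - 1L), 2:nc]
  c_ <- p[2:nr, 1:(nc - 1L)]
  d <- p[2:nr, 2:nc]
  code <- 8L * a + 2L * b + 4L * c_ + d
  s2 <- sqrt(2)
  coefs <- c(0, pi / 4 * (1 + 1 / s2), pi / (4 * s2), pi / (2 * s2),
             0, pi / 4 * (1 + 1 / s2), 0, pi / (4 * s2),
             pi / 4, pi / 2, pi / (4 * s2), pi / (4 * s2),
             pi / 4, pi / 2, 0, 0)
  sum(coefs[code + 1L])
}

boundary_perimeter <- function(mask) {
  m <- mask > 0
  p <- matrix(FALSE, nrow(m) + 2L, ncol(m) + 2L)
  p[2:(nrow(m) + 1L), 2:(ncol(m) + 1L)] <- m
  # count 4-neighbour foreground/background edges
  sum(p[, -1L] != p[, -ncol(p)]) + sum(p[-1L, ] != p[-nrow(p), ])
}

#' Cell morphology: area, perimeter, circularity
#'
#' Area is the foreground pixel count; the perimeter estimator is the Crofton
#' 4-direction formula by default (a `boundary` estimator counting
#' foreground/background pixel edges is available for comparison);
#' circularity is `4 * pi * A / P^2`, which is 1 for an ideal disc. Discrete
#' estimators can slightly exceed 1 on small rasterized discs; values are not
#' clipped but a warning is raised beyond 1.2 (degenerate masks). If the mask
#' has several connected components the largest is measured, with a warning.
#'
#' @param mask Binary matrix with >= 1 foreground pixel.
#' @param cell_id Identifier copied into the record.
#' @param estimator `"crofton"` (default) or `"boundary"`.
#' @return A `morphology_record` list: `cell_id`, `area`, `perimeter`,
#'   `circularity`.
#' @export
cell_morphology <- function(mask, cell_id = NA_integer_,
                            estimator = c("crofton", "boundary")) {
  estimator <- match.arg(estimator)
  m <- mask > 0
  if (!any(m)) stop("empty cell mask")
  lbl <- EBImage::bwlabel(m * 1)
  ncomp <- max(lbl)
  if (ncomp > 1L) {
    warning(sprintf("mask has %d components; measuring the largest", ncomp),
            call. = FALSE)
    sizes <- tabulate(as.integer(lbl[lbl > 0]))
    m <- lbl == which.max(sizes)
  }
  area <- sum(m)
  perim <- if (estimator == "crofton") crofton_perimeter(m)
           else boundary_perimeter(m)
  circ <- 4 * pi * area / perim^2
  if (circ > 1.2)
    warning("circularity > 1.2: mask too small for the perimeter estimator",
            call. = FALSE)
  structure(list(cell_id = cell_id, area = area, perimeter = perim,
                 circularity = circ),
            class = "morphology_record")
}

#' Morphology contrast between basal and activated cells
#'
#' Percent differences are expressed relative to the activated-class mean:
#' `percent_diff_area = (mean_basal - mean_activated) / mean_activated * 100`,
#' so a positive area value means basal cells are larger, and a negative
#' circularity value means basal cells are less circular. Welch two-sample
#' t-tests (basal minus activated) give the statistics and two-sided
#' p-values. With identical groups the percent differences are 0, t = 0 and
#' p = 1.
#'
#' @param records List of `morphology_record`s, or a data frame with columns
#'   `area` and `circularity`.
#' @param labels Class label per record (`"basal"` / `"activated"`; other
#'   labels are dropped). Each retained class needs >= 2 members.
#' @return Named list: `percent_diff_area`, `percent_diff_circularity`,
#'   `t_area`, `p_area`, `t_circularity`, `p_circularity`, and the group
#'   means.
#' @export
compare_classes <- function(records, labels) {
  df <- if (is.data.frame(records)) records
        else data.frame(area = vapply(records, `[[`, numeric(1), "area"),
                        circularity = vapply(records, `[[`, numeric(1),
                                             "circularity"))
  stopifnot(nrow(df) == length(labels))
  keep <- labels %in% c("basal", "activated")
  df <- df[keep, , drop = FALSE]; labels <- labels[keep]
  if (sum(labels == "basal") < 2L || sum(labels == "activated") < 2L)
    stop("need at least 2 cells in each of the basal and activated classes")
  bas <- df[labels == "basal", ]; act <- df[labels == "activated", ]
  welch <- function(x, y) {
    if (stats::sd(x) == 0 && stats::sd(y) == 0 && mean(x) == mean(y))
      return(list(statistic = 0, p.value = 1))
    tt <- stats::t.test(x, y, var.equal = FALSE)
    list(statistic = unname(tt$statistic), p.value = tt$p.value)
  }
  ta <- welch(bas$area, act$area)
  tc <- welch(bas$circularity, act$circularity)
  list(percent_diff_area =
         (mean(bas$area) - mean(act$area)) / mean(act$area) * 100,
       percent_diff_circularity =
         (mean(bas$circularity) - mean(act$circularity)) /
         mean(act$circularity) * 100,
       t_area = ta$statistic, p_area = ta$p.value,
       t_circularity = tc$statistic, p_circularity = tc$p.value,
       mean_area_basal = mean(bas$area), mean_area_activated = mean(act$area),
       mean_circularity_basal = mean(bas$circularity),
       mean_circularity_activated = mean(act$circularity))
}

#' Build a confusion matrix from truth and prediction labels
#'
#' @param truth,pred Label vectors (same length).
#' @param classes Fixed class order; defaults to the labels present.
#' @return Integer K x K matrix, rows = truth, columns = prediction.
#' @export
confusion_matrix <- function(truth, pred,
                             classes = sort(unique(c(truth, pred)))) {
  stopifnot(length(truth) == length(pred))
  as.matrix(table(factor(truth, classes), factor(pred, classes)))
}

#' Classification metrics from a confusion matrix
#'
#' Accuracy is trace/total. Precision, recall and F1 are macro-averaged over
#' classes; a class absent from both truth and prediction is excluded from
#' the averages with a warning, and a class that is never predicted (or never
#' true) contributes 0 to the corresponding average. MCC uses the multiclass
#' (Gorodkin) formula, which reduces to the familiar binary formula for two
#' classes; a zero denominator yields MCC 0.
#'
#' @param cm Confusion matrix (rows = truth, columns = prediction).
#' @return Named list: `accuracy`, `precision`, `recall`, `f1`, `mcc`.
#' @export
classification_metrics <- function(cm) {
  cm <- as.matrix(cm)
  total <- sum(cm)
  if (total <= 0) stop("confusion matrix is empty")
  rs <- rowSums(cm); cs <- colSums(cm); di <- diag(cm)
  present <- rs + cs > 0
  if (any(!present))
    warning("classes absent from both truth and prediction excluded from macro averages",
            call. = FALSE)
  prec_k <- ifelse(cs[present] > 0, di[present] / cs[present], 0)
  rec_k <- ifelse(rs[present] > 0, di[present] / rs[present], 0)
  f1_k <- ifelse(prec_k + rec_k > 0, 2 * prec_k * rec_k / (prec_k + rec_k), 0)
  s <- total; c_tr <- sum(di)
  denom <- sqrt((s^2 - sum(cs^2)) * (s^2 - sum(rs^2)))
  mcc <- if (denom == 0) 0 else (c_tr * s - sum(cs * rs)) / denom
  list(accuracy = c_tr / total, precision = mean(prec_k),
       recall = mean(rec_k), f1 = mean(f1_k), mcc = mcc)
}
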