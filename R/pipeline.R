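# End-to-end orchestration: detect -> filter -> crop/mask -> spot
# segmentation -> threshold classification -> tracking -> transition
# summaries, plus model-agnostic occlusion saliency, dataset-level summary
# statistics, and a YAML-round-trippable configuration.

#' Pipeline configuration
#'
#' Bundles the per-stage parameters. `confidence_threshold` (default 0.65)
#' filters detections before measurement; `percentile` (default 95) sets the
#' activation threshold from the calibration population; the calibration
#' population is the fed cells of the calibration timepoint (default frame
#' 0, the first image of the sequence). `feature` chooses the per-cell
#' spot-area statistic fed to the threshold (`max_area` by default: a single
#' large autolysosome is the morphological cue for activation; `total_area`
#' is available).
#'
#' @param detect [detect_params].
#' @param spots [spot_params].
#' @param tracker [tracker_config].
#' @param confidence_threshold Detection confidence cut in `[0, 1]`.
#' @param percentile Activation threshold percentile in `(0, 100)`.
#' @param calibration_timepoint Frame (0..4) whose fed cells calibrate the
#'   activation threshold.
#' @param feature `"max_area"` or `"total_area"`.
#' @param crop_pad Crop padding (px) around detection boxes.
#' @param seed Seed recorded in the run log.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(detect = detect_params(), spots = spot_params(),
                            tracker = tracker_config(),
                            confidence_threshold = 0.65, percentile = 95,
                            calibration_timepoint = 0L,
                            feature = c("max_area", "total_area"),
                            crop_pad = 2L, seed = 1L) {
  feature <- match.arg(feature)
  stopifnot(confidence_threshold >= 0, confidence_threshold <= 1,
            percentile > 0, percentile < 100,
            calibration_timepoint %in% 0:4)
  structure(list(detect = detect, spots = spots, tracker = tracker,
                 confidence_threshold = confidence_threshold,
                 percentile = percentile,
                 calibration_timepoint = as.integer(calibration_timepoint),
                 feature = feature, crop_pad = as.integer(crop_pad),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Serialize / parse a pipeline configuration as YAML
#'
#' `parse(serialize(config))` is the identity.
#'
#' @param config A [pipeline_config].
#' @return `config_to_yaml`: a YAML string. `config_from_yaml`: the
#'   [pipeline_config].
#' @export
config_to_yaml <- function(config) {
  yaml::as.yaml(lapply(unclass(config), function(x)
    if (is.list(x)) unclass(x) else x))
}

#' @param text YAML text produced by [config_to_yaml] (or a file path).
#' @rdname config_to_yaml
#' @export
config_from_yaml <- function(text) {
  lst <- if (file.exists(text[1L]) && length(text) == 1L)
    yaml::read_yaml(text) else yaml::yaml.load(paste(text, collapse = "\n"))
  pipeline_config(
    detect = do.call(detect_params, lst$detect),
    spots = do.call(spot_params, lst$spots),
    tracker = do.call(tracker_config, lst$tracker),
    confidence_threshold = lst$confidence_threshold,
    percentile = lst$percentile,
    calibration_timepoint = lst$calibration_timepoint,
    feature = lst$feature, crop_pad = lst$crop_pad, seed = lst$seed)
}

#' Summarize autophagy-state transitions over a tracked sequence
#'
#' Counts cells per class per timepoint, records each track's ordered label
#' sequence, and reports the percentage of activated cells per timepoint.
#' The percentage denominator excludes unidentified cells:
#' `activated / (basal + activated) * 100`.
#'
#' @param tracks Predicted tracks ([track_sequence]) or `NULL` to summarize
#'   labels without track sequences.
#' @param labels Data frame with columns `timepoint`, `label` and, when
#'   tracks are given, `track_id` (one row per tracked link).
#' @param condition Condition tag copied into the summary.
#' @return A `transition_summary` list: `counts` (timepoint x class),
#'   `percent_activated` (per timepoint), `track_labels` (named list of label
#'   sequences), `condition`.
#' @export
summarize_transitions <- function(tracks, labels, condition = "fed") {
  stopifnot(all(c("timepoint", "label") %in% names(labels)))
  if (!all(labels$label %in% CELL_LABELS))
    stop("labels outside the three-class set")
  tps <- sort(unique(labels$timepoint))
  counts <- t(vapply(tps, function(t)
    table(factor(labels$label[labels$timepoint == t], CELL_LABELS)),
    numeric(length(CELL_LABELS))))
  dimnames(counts) <- list(timepoint = tps, class = CELL_LABELS)
  denom <- counts[, "basal"] + counts[, "activated"]
  pct <- ifelse(denom > 0, counts[, "activated"] / denom * 100, NA_real_)
  track_labels <- list()
  if (!is.null(tracks)) {
    if (!"track_id" %in% names(labels))
      stop("labels need a track_id column when tracks are supplied")
    link_keys <- unlist(lapply(tracks, function(tr)
      paste(tr$track_id, tr$links$timepoint)))
    bad <- !paste(labels$track_id, labels$timepoint) %in% link_keys
    if (any(bad))
      stop("label attached to a nonexistent track link")
    for (tr in tracks) {
      sel <- labels$track_id == tr$track_id
      if (!any(sel)) next
      lb <- labels[sel, ]
      lb <- lb[order(lb$timepoint), ]
      track_labels[[as.character(tr$track_id)]] <- lb$label
    }
  }
  structure(list(counts = counts, percent_activated = pct,
                 track_labels = track_labels, condition = condition),
            class = "transition_summary")
}

#' @export
print.transition_summary <- function(x, ...) {
  cat(sprintf("transition_summary (%s):\n", x$condition))
  print(x$counts)
  cat("percent activated:",
      paste(sprintf("%.1f", x$percent_activated), collapse = " "), "\n")
  invisible(x)
}

#' Occlusion saliency map for an arbitrary cell classifier
#'
#' Model-agnostic input-space saliency: each patch on a stride grid is
#' replaced by the fill value (the image's background median by default) and
#' the drop in the predicted class score is recorded. The per-position drops
#' (clipped at 0) form the saliency grid, which is nearest-neighbour
#' upsampled to the image size.
#'
#' @param classifier Function taking the cell image and returning a numeric
#'   score vector (the maximum-score class of the unoccluded image is
#'   tracked); must be deterministic and finite.
#' @param cell_image Numeric matrix, or named list of channel matrices (all
#'   channels are occluded together).
#' @param patch Patch side length (<= image size).
#' @param stride Grid stride; `stride = patch` gives non-overlapping patches.
#' @param fill Occlusion fill value; default the median of the (first
#'   channel) image.
#' @return Matrix of the image size (attribute `grid` holds the raw
#'   grid of score drops).
#' @export
occlusion_saliency <- function(classifier, cell_image, patch, stride = patch,
                               fill = NULL) {
  chs <- if (is.matrix(cell_image)) list(img = cell_image) else cell_image
  d <- dim(chs[[1L]])
  stopifnot(patch >= 1, patch <= min(d), stride >= 1)
  if (is.null(fill)) fill <- stats::median(chs[[1L]])
  base <- classifier(cell_image)
  if (any(!is.finite(base))) stop("classifier returned non-finite scores")
  cls <- which.max(base)
  rows <- seq(1L, d[1L], by = stride)
  cols <- seq(1L, d[2L], by = stride)
  grid <- matrix(0, length(rows), length(cols))
  for (ri in seq_along(rows)) {
    for (ci in seq_along(cols)) {
      r0 <- rows[ri]; c0 <- cols[ci]
      r1 <- min(d[1L], r0 + patch - 1L); c1 <- min(d[2L], c0 + patch - 1L)
      occ <- lapply(chs, function(m) { m[r0:r1, c0:c1] <- fill; m })
      sc <- classifier(if (is.matrix(cell_image)) occ$img else occ)
      if (any(!is.finite(sc))) stop("classifier returned non-finite scores")
      grid[ri, ci] <- max(0, base[cls] - sc[cls])
    }
  }
  up <- grid[pmin(length(rows), (seq_len(d[1L]) - 1L) %/% stride + 1L),
             pmin(length(cols), (seq_len(d[2L]) - 1L) %/% stride + 1L),
             drop = FALSE]
  attr(up, "grid") <- grid
  up
}

#' Dataset-level summary statistics over annotated frames
#'
#' Pooled class percentages over all cells, the minimum and maximum cell
#' count per image, and the basal-versus-activated morphology contrast (via
#' [cell_morphology] and [compare_classes]). This is the entry point for
#' reproducing the annotated dataset's published summary statistics on a
#' full download, and for checking planted statistics on generated data.
#'
#' @param frames List of [annotated_frame]s (>= 1, with >= 1 cell in total).
#' @param out_json Optional path for a JSON report.
#' @return Named list: `class_percentages`, `cells_per_image_min`,
#'   `cells_per_image_max`, `n_cells`, `morphology` (the [compare_classes]
#'   output, or `NULL` if a class has < 2 members).
#' @export
replicate_dataset_statistics <- function(frames, out_json = NULL) {
  if (length(frames) == 0L) stop("need at least one annotated frame")
  per_image <- vapply(frames, function(f) length(f$cells), integer(1))
  all_labels <- unlist(lapply(frames, function(f)
    vapply(f$cells, `[[`, character(1), "label")))
  if (length(all_labels) == 0L) stop("zero cells in total")
  pct <- 100 * table(factor(all_labels, CELL_LABELS)) / length(all_labels)
  morphs <- do.call(rbind, lapply(frames, function(f)
    do.call(rbind, lapply(f$cells, function(cl) {
      m <- cell_morphology(cl$mask, cl$cell_id)
      data.frame(area = m$area, circularity = m$circularity,
                 label = cl$label)
    }))))
  morphology <- if (sum(morphs$label == "basal") >= 2L &&
                    sum(morphs$label == "activated") >= 2L)
    compare_classes(morphs[, c("area", "circularity")], morphs$label)
  else NULL
  out <- list(class_percentages = stats::setNames(as.numeric(pct),
                                                  names(pct)),
              cells_per_image_min = min(per_image),
              cells_per_image_max = max(per_image),
              n_cells = length(all_labels), morphology = morphology)
  if (!is.null(out_json))
    jsonlite::write_json(out, out_json, auto_unbox = TRUE, digits = NA)
  out
}

measure_detection <- function(frame, det, config) {
  crop <- crop_cell(frame$channels, det$box, pad = config$crop_pad)
  cb <- attr(crop, "crop_box")
  mask_crop <- if (!is.null(det$mask))
    crop_cell(list(m = det$mask), det$box, pad = config$crop_pad)$m
  else matrix(TRUE, nrow(crop$green), ncol(crop$green))
  masked <- apply_mask(crop, mask_crop)
  spot <- segment_spots(frame$channels$red,
                        if (!is.null(det$mask)) det$mask else
                          full_mask_from_box(frame, det$box),
                        config$spots)
  feat <- embed_cell(masked, mask_crop)
  list(spot = spot, feature = feat, crop_box = cb)
}

full_mask_from_box <- function(frame, box) {
  d <- frame_dim(frame)
  m <- matrix(FALSE, d[1L], d[2L])
  m[(box[["y0"]] + 1):box[["y1"]], (box[["x0"]] + 1):box[["x1"]]] <- TRUE
  m
}

#' Run the full analysis pipeline on one sequence
#'
#' Per frame: reference detection, confidence filtering, crop + mask
#' isolation, red-spot segmentation; then threshold classification
#' (calibrated on the fed calibration frame, or on `calibration_values` /
#' `threshold` supplied for starved sequences), tracking across the five
#' frames, and the transition summary. The run is deterministic: identical
#' input and configuration reproduce the bundle (and any written files)
#' exactly.
#'
#' @param seq A [cell_sequence].
#' @param config A [pipeline_config].
#' @param out_dir Optional output directory; when given, writes
#'   `spots.csv`, `labels.csv`, `tracks.csv`, `summary.json`,
#'   `run_log.json`.
#' @param calibration_values Optional raw calibration feature values from a
#'   fed sequence of the same replicate; they are normalized jointly with
#'   this sequence's features and the threshold is calibrated on them.
#' @param threshold Optional precomputed activation threshold (overrides
#'   calibration).
#' @return A `pipeline_result` list: `spot_table`, `labels`, `threshold`,
#'   `tracks`, `summary`, `excluded`, `config`.
#' @export
run_pipeline <- function(seq, config = pipeline_config(), out_dir = NULL,
                         calibration_values = NULL, threshold = NULL) {
  stopifnot(inherits(seq, "cell_sequence"))
  dets_per_frame <- vector("list", 5L)
  feats_per_frame <- vector("list", 5L)
  spot_rows <- list()
  for (f in seq$frames) {
    t <- f$timepoint
    dets <- tryCatch(
      filter_by_confidence(reference_detect(f, params = config$detect),
                           config$confidence_threshold),
      error = function(e) stop(sprintf("stage detect failed at frame %d: %s",
                                       t, conditionMessage(e))))
    feats <- vector("list", length(dets))
    for (j in seq_along(dets)) {
      m <- tryCatch(measure_detection(f, dets[[j]], config),
                    error = function(e)
                      stop(sprintf("stage measure failed at frame %d: %s",
                                   t, conditionMessage(e))))
      feats[[j]] <- m$feature
      dets[[j]]$cell_id <- j
      spot_rows[[length(spot_rows) + 1L]] <-
        data.frame(timepoint = t, det_index = j,
                   spot_count = m$spot$spot_count,
                   total_area = m$spot$total_area,
                   max_area = m$spot$max_area,
                   no_spots = m$spot$no_spots,
                   confidence = dets[[j]]$confidence)
    }
    dets_per_frame[[t + 1L]] <- dets
    feats_per_frame[[t + 1L]] <- feats
  }
  spot_table <- if (length(spot_rows))
    do.call(rbind, c(spot_rows, list(make.row.names = FALSE)))
  else data.frame(timepoint = integer(), det_index = integer(),
                  spot_count = integer(), total_area = numeric(),
                  max_area = numeric(), no_spots = logical(),
                  confidence = numeric())

  # normalize within the replicate and log-transform; fed calibration values
  # (raw features) belong to the same replicate and are transformed jointly
  measurable <- !spot_table$no_spots & spot_table[[config$feature]] > 0
  spot_table$transformed <- rep(NA_real_, nrow(spot_table))
  raw <- spot_table[[config$feature]][measurable]
  calib <- numeric()
  if (!is.null(calibration_values)) {
    allv <- c(calibration_values, raw)
    tv <- if (length(allv))
      normalize_and_log(allv, rep(seq$replicate_id, length(allv)))
    else numeric()
    calib <- tv[seq_along(calibration_values)]
    spot_table$transformed[measurable] <- tv[-seq_along(calibration_values)]
  } else if (any(measurable)) {
    spot_table$transformed[measurable] <-
      normalize_and_log(raw, rep(seq$replicate_id, length(raw)))
    if (seq$condition != "fed" && is.null(threshold))
      warning(paste("calibrating the activation threshold on a starved",
                    "sequence's own calibration frame; supply fed",
                    "calibration_values for the published procedure"),
              call. = FALSE)
    calib <- spot_table$transformed[measurable &
                                      spot_table$timepoint ==
                                        config$calibration_timepoint]
  }
  if (is.null(threshold))
    threshold <- if (length(calib) >= 2L)
      activation_threshold(calib, config$percentile) else NA_real_

  labels <- data.frame(timepoint = integer(), det_index = integer(),
                       label = character())
  if (is.finite(threshold) && nrow(spot_table) > 0) {
    cls <- classify_by_threshold(
      data.frame(cell_id = seq_len(nrow(spot_table)),
                 feature = spot_table$transformed,
                 no_spots = !measurable), threshold)
    labels <- data.frame(timepoint = spot_table$timepoint[cls$cell_id],
                         det_index = spot_table$det_index[cls$cell_id],
                         label = cls$label)
  }

  tracks <- if (any(lengths(dets_per_frame) > 0))
    track_sequence(dets_per_frame, feats_per_frame, config$tracker)
  else list()

  # attach labels to track links for the transition summary
  tt <- tracks_table(tracks)
  lab_links <- merge(tt[, c("track_id", "timepoint", "cell_id")],
                     labels, by.x = c("timepoint", "cell_id"),
                     by.y = c("timepoint", "det_index"))
  summary <- summarize_transitions(
    tracks, lab_links[, c("timepoint", "track_id", "label")],
    seq$condition)

  result <- structure(
    list(spot_table = spot_table, labels = labels, threshold = threshold,
         tracks = tracks, summary = summary,
         excluded = spot_table$det_index[!measurable],
         config = config),
    class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_bundle(result, seq, out_dir)
  result
}

# compact deterministic config checksum (31-bit polynomial rolling hash)
fnv1a_hash <- function(text) {
  h <- 0
  for (b in utf8ToInt(text)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Extract raw calibration feature values from a fed pipeline run
#'
#' Convenience for the two-sequence workflow: run the pipeline on the fed
#' sequence, pull its calibration-frame raw features with this function, and
#' pass them as `calibration_values` when running the starved sequence.
#'
#' @param result A `pipeline_result` from a fed sequence.
#' @param config The [pipeline_config] (defaults to the result's).
#' @return Raw feature values of the fed calibration frame's cells with
#'   spots.
#' @export
fed_calibration <- function(result, config = result$config) {
  st <- result$spot_table
  sel <- !st$no_spots & st[[config$feature]] > 0 &
    st$timepoint == config$calibration_timepoint
  st[[config$feature]][sel]
}

write_pipeline_bundle <- function(result, seq, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ok <- tryCatch({
    utils::write.csv(result$spot_table, file.path(out_dir, "spots.csv"),
                     row.names = FALSE)
    utils::write.csv(result$labels, file.path(out_dir, "labels.csv"),
                     row.names = FALSE)
    utils::write.csv(tracks_table(result$tracks),
                     file.path(out_dir, "tracks.csv"), row.names = FALSE)
    s <- result$summary
    jsonlite::write_json(
      list(condition = s$condition,
           counts = as.data.frame.matrix(s$counts),
           percent_activated = unname(s$percent_activated),
           threshold = result$threshold,
           excluded_no_spot = result$excluded),
      file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA)
    cfg_yaml <- config_to_yaml(result$config)
    jsonlite::write_json(
      list(seed = result$config$seed,
           config_hash = fnv1a_hash(cfg_yaml),
           package_version = as.character(utils::packageVersion("phagoscope")),
           config = cfg_yaml, condition = seq$condition,
           replicate_id = seq$replicate_id,
           n_tracks = length(result$tracks)),
      file.path(out_dir, "run_log.json"), auto_unbox = TRUE, digits = NA)
    TRUE
  }, error = function(e) {
    unlink(out_dir, recursive = TRUE)
    stop(sprintf("writing outputs failed (partial outputs removed): %s",
                 conditionMessage(e)))
  })
  invisible(ok)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("pipeline_result: %d detections, threshold %.4f, %d tracks\n",
              nrow(x$spot_table), x$threshold, length(x$tracks)))
  print(x$summary)
  invisible(x)
}
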