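# Feature-based multi-object cell tracker: Hungarian data association on a
# spatial + appearance + overlap cost, no motion model (the last observed
# position is the predictor), an active/inactive track lifecycle that keeps
# inactive tracks for the whole sequence so cells can be re-identified after
# detection gaps, and division handling that links an unmatched detection to
# a matched parent when their boxes overlap. Track-quality metrics (identity
# switches, fragmentation, purity) evaluate the result against ground-truth
# identities.

#' Deterministic reference cell embedding
#'
#' A hand-crafted appearance descriptor standing behind the pluggable
#' embedding contract (crop of a masked cell in, fixed-length vector out):
#' per-channel 16-bin intensity histograms over the mask pixels (binned on
#' the crop's own intensity range, making the descriptor robust to uniform
#' gain), plus relative mask area, circularity, and mean channel intensities.
#' The vector is L2-normalized. Any learned embedding with the same contract
#' can replace it.
#'
#' @param channels Named list of cropped channel matrices (at least `green`
#'   and `red`).
#' @param mask Binary matrix, same shape as the channels, nonempty.
#' @param nbins Histogram bins per channel.
#' @return Numeric feature vector with attribute `extractor_id`.
#' @export
embed_cell <- function(channels, mask, nbins = 16L) {
  mask <- mask > 0
  if (!any(mask)) stop("empty mask")
  use <- intersect(c("green", "red"), names(channels))
  feats <- numeric()
  for (ch in use) {
    v <- unclass(channels[[ch]])[mask]
    top <- max(v, 1e-9)
    h <- tabulate(pmin(nbins, floor(v / top * nbins) + 1L), nbins)
    feats <- c(feats, h / length(v))
  }
  morph <- cell_morphology(mask)
  feats <- c(feats,
             area = sum(mask) / length(mask),
             circ = morph$circularity,
             vapply(use, function(ch)
               mean(unclass(channels[[ch]])[mask]) / 65535, numeric(1)))
  nrm <- sqrt(sum(feats^2))
  out <- if (nrm > 0) feats / nrm else feats
  attr(out, "extractor_id") <- "histogram-morphology-v1"
  out
}

cosine_similarity <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

#' Tracker configuration
#'
#' Association cost between a candidate track and a detection:
#' `w_spatial * d/D + w_feature * (1 - cos)/2 + w_overlap * (1 - IoU)`,
#' with centroid distance `d` normalized by the gate radius `D`; pairs beyond
#' the gate are forbidden. Inactive candidates (re-identification) pay a
#' fixed surcharge on top. A division links an unmatched detection to a
#' matched parent when the box IoU with the parent's previous box reaches
#' `theta_div`: the default 0.15 reflects daughters displaced by about one
#' parent radius, whose boxes overlap the parent's by roughly 0.2 in IoU.
#'
#' @param w_spatial,w_feature,w_overlap Non-negative cost weights summing
#'   to 1.
#' @param gate_radius Gate radius `D` in pixels, or `"auto"` (3x the median
#'   detected cell diameter at the current frame).
#' @param reid_surcharge Cost added for inactive candidates.
#' @param theta_div Box-IoU threshold for declaring a division child.
#' @return A `tracker_config` list.
#' @export
tracker_config <- function(w_spatial = 0.4, w_feature = 0.4, w_overlap = 0.2,
                           gate_radius = "auto", reid_surcharge = 0.1,
                           theta_div = 0.15) {
  w <- c(w_spatial, w_feature, w_overlap)
  if (any(w < 0) || abs(sum(w) - 1) > 1e-8)
    stop("weights must be non-negative and sum to 1")
  structure(list(w_spatial = w_spatial, w_feature = w_feature,
                 w_overlap = w_overlap, gate_radius = gate_radius,
                 reid_surcharge = reid_surcharge, theta_div = theta_div),
            class = "tracker_config")
}

det_centroid <- function(det) {
  if (!is.null(det$mask)) {
    idx <- which(det$mask, arr.ind = TRUE)
    c(x = mean(idx[, 2L]), y = mean(idx[, 1L]))
  } else bbox_center(det$box)
}

resolve_gate <- function(config, detections) {
  if (!identical(config$gate_radius, "auto")) return(config$gate_radius)
  if (length(detections) == 0L) return(1)
  diam <- vapply(detections, function(d)
    max(d$box[["x1"]] - d$box[["x0"]], d$box[["y1"]] - d$box[["y0"]]),
    numeric(1))
  3 * stats::median(diam)
}

#' Build the association cost matrix
#'
#' Rows are candidate tracks (active first, then inactive), columns are the
#' current detections. Entries follow the [tracker_config] cost; pairs with
#' centroid distance beyond the gate are `Inf`.
#'
#' @param candidates List of track objects (fields `last_centroid`,
#'   `last_box`, `last_feature`, `status`).
#' @param detections List of [detection]s.
#' @param features List of feature vectors, one per detection.
#' @param config A [tracker_config].
#' @param gate Resolved gate radius (pixels).
#' @return Numeric matrix (possibly containing `Inf`).
#' @export
build_cost_matrix <- function(candidates, detections, features, config,
                              gate = resolve_gate(config, detections)) {
  if (length(features) != length(detections))
    stop("features and detections must align")
  C <- matrix(Inf, length(candidates), length(detections))
  if (length(candidates) == 0L || length(detections) == 0L) return(C)
  cents <- lapply(detections, det_centroid)
  for (i in seq_along(candidates)) {
    tr <- candidates[[i]]
    for (j in seq_along(detections)) {
      d <- sqrt(sum((tr$last_centroid - cents[[j]])^2))
      if (d > gate) next
      cost <- config$w_spatial * d / gate +
        config$w_feature *
          (1 - cosine_similarity(tr$last_feature, features[[j]])) / 2 +
        config$w_overlap * (1 - box_iou(tr$last_box, detections[[j]]$box))
      if (tr$status == "inactive") cost <- cost + config$reid_surcharge
      C[i, j] <- cost
    }
  }
  C
}

new_track <- function(track_id, t, det, feature, det_index,
                      parent_track_id = NA_integer_) {
  list(track_id = track_id,
       links = data.frame(timepoint = t, det_index = det_index,
                          cell_id = if (!is.null(det$cell_id)) det$cell_id
                                    else NA_integer_),
       status = "active", last_feature = feature,
       last_centroid = det_centroid(det), last_box = det$box,
       parent_track_id = parent_track_id)
}

#' Initialize tracker state
#'
#' Frame 0 creates one active track per detection.
#'
#' @param detections List of [detection]s at timepoint 0.
#' @param features Matching list of feature vectors.
#' @param config A [tracker_config].
#' @return A `tracker_state` list.
#' @export
tracker_init <- function(detections, features, config = tracker_config()) {
  tracks <- lapply(seq_along(detections), function(j)
    new_track(j, 0L, detections[[j]], features[[j]], j))
  structure(list(tracks = tracks, next_id = length(detections) + 1L,
                 config = config, t = 0L),
            class = "tracker_state")
}

#' Advance the tracker by one frame
#'
#' Jointly associates active and inactive candidate tracks to the frame's
#' detections with [hungarian] on [build_cost_matrix]; matched tracks extend
#' and (re)activate, unmatched tracks turn inactive but keep their history
#' for the rest of the sequence, and each unmatched detection either becomes
#' a division child of a matched parent (box IoU with the parent's previous
#' box `>= theta_div`) or starts a new track. No track ever receives two
#' detections in one frame.
#'
#' @param state A `tracker_state`.
#' @param detections List of [detection]s at the new timepoint.
#' @param features Matching list of feature vectors.
#' @param t Timepoint of the detections (defaults to the next frame).
#' @return The updated `tracker_state`.
#' @export
tracker_step <- function(state, detections, features, t = state$t + 1L) {
  stopifnot(inherits(state, "tracker_state"))
  if (length(features) != length(detections))
    stop("features and detections must align")
  di <- vapply(detections, function(d)
    if (!is.null(d$cell_id)) as.integer(d$cell_id) else NA_integer_, integer(1))
  if (anyDuplicated(di[!is.na(di)]))
    stop("duplicate detection references in one frame")
  cfg <- state$config
  tracks <- state$tracks
  status <- vapply(tracks, `[[`, character(1), "status")
  cand_idx <- c(which(status == "active"), which(status == "inactive"))
  gate <- resolve_gate(cfg, detections)
  prev_box <- lapply(tracks, `[[`, "last_box")

  C <- build_cost_matrix(tracks[cand_idx], detections, features, cfg, gate)
  asg <- hungarian(C)
  matched_det <- integer(0)
  matched_track <- integer(0)
  if (nrow(asg$pairs) > 0) {
    for (k in seq_len(nrow(asg$pairs))) {
      ti <- cand_idx[asg$pairs[k, "row"]]
      j <- asg$pairs[k, "col"]
      tr <- tracks[[ti]]
      tr$links <- rbind(tr$links,
                        data.frame(timepoint = t, det_index = j,
                                   cell_id = di[j]))
      tr$status <- "active"
      tr$last_feature <- features[[j]]
      tr$last_centroid <- det_centroid(detections[[j]])
      tr$last_box <- detections[[j]]$box
      tracks[[ti]] <- tr
      matched_det <- c(matched_det, j)
      matched_track <- c(matched_track, ti)
    }
  }
  for (ti in setdiff(seq_along(tracks), matched_track))
    tracks[[ti]]$status <- "inactive"

  for (j in setdiff(seq_along(detections), matched_det)) {
    parent <- NA_integer_
    if (length(matched_track)) {
      ious <- vapply(matched_track, function(ti)
        box_iou(prev_box[[ti]], detections[[j]]$box), numeric(1))
      best <- which.max(ious)
      if (length(best) && ious[best] >= cfg$theta_div)
        parent <- tracks[[matched_track[best]]]$track_id
    }
    tracks[[length(tracks) + 1L]] <-
      new_track(state$next_id, t, detections[[j]], features[[j]], j, parent)
    state$next_id <- state$next_id + 1L
  }
  state$tracks <- tracks
  state$t <- t
  state
}

#' Track a whole five-frame sequence
#'
#' Applies [tracker_init] and [tracker_step] over the frames and returns all
#' tracks, active and inactive, with their full histories. Deterministic
#' given inputs and configuration.
#'
#' @param seq_detections List (one element per frame, in time order) of lists
#'   of [detection]s. Each detection may carry a `cell_id` field referencing
#'   the annotation it came from.
#' @param seq_features Parallel list of feature-vector lists; by default
#'   computed with [embed_cell] from each detection's mask (requires
#'   `channels` attached to each frame element via the `channels` argument).
#' @param config A [tracker_config].
#' @return List of track objects.
#' @export
track_sequence <- function(seq_detections, seq_features,
                           config = tracker_config()) {
  if (length(seq_detections) == 0L) stop("empty frame list")
  if (length(seq_features) != length(seq_detections))
    stop("features must align with detections")
  state <- tracker_init(seq_detections[[1L]], seq_features[[1L]], config)
  for (t in seq_along(seq_detections)[-1L])
    state <- tracker_step(state, seq_detections[[t]], seq_features[[t]],
                          t - 1L)
  state$tracks
}

#' Ground-truth detections and features for a generated sequence
#'
#' Converts a generated sequence's annotated cells into per-frame detection
#' lists (confidence 1, true masks and boxes, `cell_id` attached) plus
#' reference embeddings, the standard input for tracker evaluation.
#'
#' @param sim The list returned by [generate_sequence].
#' @return List with `detections` and `features`, each one list per frame.
#' @export
truth_detections <- function(sim) {
  seq <- sim$sequence
  dets <- lapply(seq$frames, function(f)
    lapply(f$cells, function(cl) {
      d <- detection(cl$box, 1, cl$mask)
      d$cell_id <- cl$cell_id
      d
    }))
  feats <- lapply(seq$frames, function(f)
    lapply(f$cells, function(cl) {
      crop <- crop_cell(f$channels, cl$box, pad = 2)
      mcrop <- crop_cell(list(m = cl$mask), cl$box, pad = 2)$m
      embed_cell(apply_mask(crop, mcrop), mcrop)
    }))
  list(detections = dets, features = feats)
}

#' Tracking quality against ground-truth identities
#'
#' Links are matched to truth by `(timepoint, cell_id)`. Fragmentation is,
#' per truth track, the number of distinct predicted tracks covering it minus
#' one, summed. Identity switches count adjacent link pairs within a
#' predicted track whose underlying truth identity changes; when
#' `collapse_divisions` is `TRUE` (default) a change from a truth track to
#' one of its descendants is a legitimate lineage continuation, not a switch.
#' Purity is the fraction of each predicted track's links belonging to its
#' majority truth identity, averaged over predicted tracks.
#'
#' @param tracks Predicted tracks (from [track_sequence]).
#' @param truth A `synth_truth` object, or a data frame with columns
#'   `timepoint`, `cell_id`, `track_id` (and optionally `parent_track_id`).
#' @param collapse_divisions Treat parent-to-descendant identity changes as
#'   continuations?
#' @return Named list: `identity_switches`, `fragmentation`, `track_purity`.
#' @export
tracking_metrics <- function(tracks, truth, collapse_divisions = TRUE) {
  cells <- if (inherits(truth, "synth_truth")) truth$cells else truth
  key <- paste(cells$timepoint, cells$cell_id)
  truth_of <- stats::setNames(cells$track_id, key)
  parent_of <- if ("parent_track_id" %in% names(cells)) {
    tr <- unique(cells[, c("track_id", "parent_track_id")])
    stats::setNames(tr$parent_track_id, tr$track_id)
  } else stats::setNames(integer(), character())

  is_descendant <- function(child, ancestor) {
    k <- 0L
    while (!is.na(child) && k < 10L) {
      if (child == ancestor) return(TRUE)
      child <- if (as.character(child) %in% names(parent_of))
        parent_of[[as.character(child)]] else NA_integer_
      k <- k + 1L
    }
    FALSE
  }

  switches <- 0L
  purities <- numeric()
  cover <- list()  # truth track -> set of predicted tracks covering it
  for (tr in tracks) {
    links <- tr$links[order(tr$links$timepoint), , drop = FALSE]
    k <- paste(links$timepoint, links$cell_id)
    if (any(!k %in% names(truth_of)))
      stop("predicted link references a detection absent from the truth")
    ids <- unname(truth_of[k])
    for (tid in unique(ids)) {
      cover[[as.character(tid)]] <-
        union(cover[[as.character(tid)]], tr$track_id)
    }
    if (length(ids) > 1L) {
      for (q in seq_len(length(ids) - 1L)) {
        if (ids[q] != ids[q + 1L]) {
          lineage <- collapse_divisions &&
            (is_descendant(ids[q + 1L], ids[q]) ||
               is_descendant(ids[q], ids[q + 1L]))
          if (!lineage) switches <- switches + 1L
        }
      }
    }
    maj <- names(which.max(table(ids)))
    purities <- c(purities, mean(ids == as.integer(maj)))
  }
  frag <- sum(vapply(cover, function(s) length(s) - 1L, integer(1)))
  list(identity_switches = switches, fragmentation = frag,
       track_purity = if (length(purities)) mean(purities) else NA_real_)
}

#' Export tracks as a tidy table
#'
#' @param tracks List of track objects.
#' @return Data frame: `track_id`, `timepoint`, `cell_id`, `det_index`,
#'   `status`, `parent_track_id`.
#' @export
tracks_table <- function(tracks) {
  if (length(tracks) == 0L)
    return(data.frame(track_id = integer(), timepoint = integer(),
                      cell_id = integer(), det_index = integer(),
                      status = character(), parent_track_id = integer()))
  do.call(rbind, c(lapply(tracks, function(tr) {
    data.frame(track_id = tr$track_id, timepoint = tr$links$timepoint,
               cell_id = tr$links$cell_id, det_index = tr$links$det_index,
               status = tr$status, parent_track_id = tr$parent_track_id)
  }), list(make.row.names = FALSE)))
}
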