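# Seeded generator of synthetic tandem-reporter time-lapse sequences with
# complete ground truth: per-cell masks, boxes, labels, persistent track
# identities, division events, starvation transition times, and the planted
# red/green punctum raster (the oracle for the spot-segmentation stage).
#
# Reporter logic emulated: basal cells carry few small puncta rendered in
# BOTH green and red (autophagosomes, yellow); activated cells carry more and
# larger puncta rendered in red ONLY (autolysosomes; EGFP quenched).

#' Configuration for the synthetic sequence generator
#'
#' Defaults describe the standing study conditions for all tests: modest
#' image size, well-separated compact cells, a clear punctum-size contrast
#' between basal and activated states, mid-sequence starvation transitions,
#' and a morphology contrast (basal cells ~12.65% larger in expected area and
#' less circular via stronger boundary perturbation) mirroring the annotated
#' dataset's reported statistics.
#'
#' @param image_size Image side length in pixels.
#' @param n_cells Initial cell count.
#' @param condition `"fed"` or `"starved"`.
#' @param cell_radius_mean,cell_radius_sd Cell base radius distribution (px).
#' @param motion_sd Centroid drift per frame (px, per axis).
#' @param division_prob Per-cell, per-frame division probability.
#' @param transition_time_mean,transition_time_sd Starved-cell transition
#'   frame distribution (frames); draws are rounded and clamped to 0..5, with
#'   values >= 5 meaning "never transitions".
#' @param basal_puncta_count_range,activated_puncta_count_range Integer ranges
#'   for punctum counts per cell per frame.
#' @param puncta_radius_range Integer punctum radius range (px) for basal
#'   cells; activated radii are scaled by `activated_puncta_radius_scale`
#'   (must be > 1: activated puncta are larger).
#' @param background_level,noise_sd Camera background and Gaussian read noise
#'   (intensity counts; channels are quantized to integers in 0..65535).
#' @param cell_intensity Diffuse cytosolic reporter signal added inside cells
#'   (green and red).
#' @param puncta_intensity Punctum amplitude above the cytosol.
#' @param basal_area_excess Fractional excess of basal expected cell area over
#'   activated (0.1265 plants the dataset's reported 12.65% contrast).
#' @param basal_perturbation,activated_perturbation Radial boundary
#'   perturbation SD (fraction of radius); larger values give less circular
#'   outlines, so basal > activated plants the circularity contrast.
#' @param unidentified_fraction Fraction of cells rendered at low contrast and
#'   labeled `unidentified` (0 for clean tests).
#' @param unidentified_intensity Diffuse signal for unidentified cells.
#' @param n_vertices_range Integer range of blob polygon vertices.
#' @param class_mix Optional named probabilities (`basal`, `activated`,
#'   `unidentified`): when given, each cell's class is drawn once at creation
#'   and held static (no transitions); used to plant class-proportion mixes.
#' @param seed Integer RNG seed; identical configs reproduce sequences
#'   bit-for-bit.
#' @return A validated `synth_config` list.
#' @export
synth_config <- function(image_size = 256L, n_cells = 12L,
                         condition = c("fed", "starved"),
                         cell_radius_mean = 16, cell_radius_sd = 2.5,
                         motion_sd = 2, division_prob = 0.02,
                         transition_time_mean = 2.5, transition_time_sd = 1,
                         basal_puncta_count_range = c(1L, 4L),
                         activated_puncta_count_range = c(5L, 10L),
                         puncta_radius_range = c(2L, 4L),
                         activated_puncta_radius_scale = 1.6,
                         background_level = 200, noise_sd = 8,
                         cell_intensity = 600, puncta_intensity = 8000,
                         basal_area_excess = 0.1265,
                         basal_perturbation = 0.17,
                         activated_perturbation = 0.12,
                         unidentified_fraction = 0,
                         unidentified_intensity = 120,
                         n_vertices_range = c(8L, 16L),
                         class_mix = NULL,
                         seed = 1L) {
  condition <- match.arg(condition)
  cfg <- list(image_size = as.integer(image_size), n_cells = as.integer(n_cells),
              condition = condition, cell_radius_mean = cell_radius_mean,
              cell_radius_sd = cell_radius_sd, motion_sd = motion_sd,
              division_prob = division_prob,
              transition_time_mean = transition_time_mean,
              transition_time_sd = transition_time_sd,
              basal_puncta_count_range = as.integer(basal_puncta_count_range),
              activated_puncta_count_range = as.integer(activated_puncta_count_range),
              puncta_radius_range = as.integer(puncta_radius_range),
              activated_puncta_radius_scale = activated_puncta_radius_scale,
              background_level = background_level, noise_sd = noise_sd,
              cell_intensity = cell_intensity, puncta_intensity = puncta_intensity,
              basal_area_excess = basal_area_excess,
              basal_perturbation = basal_perturbation,
              activated_perturbation = activated_perturbation,
              unidentified_fraction = unidentified_fraction,
              unidentified_intensity = unidentified_intensity,
              n_vertices_range = as.integer(n_vertices_range),
              class_mix = class_mix, seed = as.integer(seed))
  stopifnot(cfg$n_cells >= 0L, cfg$cell_radius_mean > 0,
            cfg$division_prob >= 0, cfg$division_prob <= 1,
            cfg$unidentified_fraction >= 0, cfg$unidentified_fraction <= 1,
            cfg$activated_puncta_radius_scale > 1,
            all(cfg$puncta_radius_range >= 1L))
  if (!is.null(class_mix)) {
    if (!all(names(class_mix) %in% CELL_LABELS) || any(class_mix < 0))
      stop("class_mix must be named non-negative probabilities over the labels")
  }
  structure(cfg, class = "synth_config")
}

# Run code under a fixed, kind-pinned RNG state, restoring the caller's state.
with_rng <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
    get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(code)
}

# Rasterize one radial-perturbation blob into a full-frame logical mask.
# Boundary radius is a piecewise-linear function of angle through the
# perturbed vertex radii; the raster is then morphologically closed and
# opened with a small disc to smooth spikes.
radial_blob_mask <- function(dm, cx, cy, radius, n_vertices, perturb,
                             smooth = 5L) {
  ang <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  # perturbation inflates the expected enclosed area by 1 + (2/3) * perturb^2
  # (piecewise-linear boundary radius); compensate so E[area] ~ pi * radius^2
  # independently of how wiggly the outline is
  radius <- radius / sqrt(1 + (2 / 3) * perturb^2)
  vr <- radius * pmax(0.3, 1 + perturb * stats::rnorm(n_vertices))
  rmax <- max(vr) + smooth + 1
  y0 <- max(1L, floor(cy - rmax)); y1 <- min(dm[1L], ceiling(cy + rmax))
  x0 <- max(1L, floor(cx - rmax)); x1 <- min(dm[2L], ceiling(cx + rmax))
  ys <- y0:y1; xs <- x0:x1
  dy <- outer(ys - cy, rep(1, length(xs)))
  dx <- outer(rep(1, length(ys)), xs - cx)
  theta <- atan2(dy, dx) %% (2 * pi)
  rb <- stats::approx(x = c(ang, ang[1L] + 2 * pi), y = c(vr, vr[1L]),
                      xout = theta, method = "linear")$y
  win <- sqrt(dy^2 + dx^2) <= rb
  br <- EBImage::makeBrush(smooth, "disc")
  win <- EBImage::opening(EBImage::closing(win * 1, br), br) > 0
  if (!any(win)) win[round(cy) - y0 + 1L, round(cx) - x0 + 1L] <- TRUE
  mask <- matrix(FALSE, dm[1L], dm[2L])
  mask[ys, xs] <- win
  mask
}

rasterize_disc <- function(dm, cx, cy, r) {
  y0 <- max(1L, floor(cy - r)); y1 <- min(dm[1L], ceiling(cy + r))
  x0 <- max(1L, floor(cx - r)); x1 <- min(dm[2L], ceiling(cx + r))
  ys <- y0:y1; xs <- x0:x1
  inside <- outer((ys - cy)^2, rep(1, length(xs))) +
    outer(rep(1, length(ys)), (xs - cx)^2) <= r^2
  idx <- which(inside, arr.ind = TRUE)
  cbind(row = idx[, 1L] + y0 - 1L, col = idx[, 2L] + x0 - 1L)
}

# Place punctum centers inside a cell mask so each disc lies fully inside the
# mask and discs are pairwise disjoint; unplaceable puncta are dropped.
# The distance map is computed on the mask's padded bounding-box window.
place_puncta <- function(mask, radii, max_tries = 60L) {
  bb <- mask_bbox(mask)
  d <- dim(mask)
  wy0 <- max(1L, bb[["y0"]] - 1L); wy1 <- min(d[1L], bb[["y1"]] + 2L)
  wx0 <- max(1L, bb[["x0"]] - 1L); wx1 <- min(d[2L], bb[["x1"]] + 2L)
  dmap <- EBImage::distmap(mask[wy0:wy1, wx0:wx1] * 1)
  placed <- data.frame(x = numeric(), y = numeric(), radius = integer())
  for (r in radii) {
    ok <- which(dmap > r + 0.5, arr.ind = TRUE)
    if (nrow(ok) == 0L) next
    for (k in seq_len(max_tries)) {
      i <- ok[sample.int(nrow(ok), 1L), ]
      cy <- i[[1L]] + wy0 - 1L; cx <- i[[2L]] + wx0 - 1L
      if (nrow(placed) == 0L ||
          all(sqrt((placed$x - cx)^2 + (placed$y - cy)^2) >
              placed$radius + r + 2.5)) {
        placed <- rbind(placed, data.frame(x = cx, y = cy, radius = r))
        break
      }
    }
  }
  placed
}

cell_label_at <- function(cell, t, condition) {
  if (!is.null(cell$static_label)) return(cell$static_label)
  if (cell$unidentified) return("unidentified")
  if (condition == "starved" && !is.na(cell$transition_frame) &&
      t >= cell$transition_frame) "activated" else "basal"
}

draw_transition_frame <- function(cfg) {
  tf <- round_half_up(stats::rnorm(1, cfg$transition_time_mean,
                                   cfg$transition_time_sd))
  tf <- max(0, min(5, tf))
  if (tf >= 5) NA_integer_ else as.integer(tf)
}

new_synth_cell <- function(cfg, track_id, center, radius = NULL,
                           parent_track_id = NA_integer_, state = NULL) {
  if (is.null(radius))
    radius <- max(cfg$cell_radius_mean * 0.5,
                  min(cfg$cell_radius_mean * 2,
                      stats::rnorm(1, cfg$cell_radius_mean, cfg$cell_radius_sd)))
  cell <- list(track_id = track_id, center = center, base_radius = radius,
               parent_track_id = parent_track_id,
               n_vertices = sample(cfg$n_vertices_range[1L]:cfg$n_vertices_range[2L], 1L))
  if (!is.null(state)) {
    cell$unidentified <- state$unidentified
    cell$transition_frame <- state$transition_frame
    cell$static_label <- state$static_label
  } else if (!is.null(cfg$class_mix)) {
    p <- cfg$class_mix / sum(cfg$class_mix)
    cell$static_label <- sample(names(p), 1L, prob = p)
    cell$unidentified <- identical(cell$static_label, "unidentified")
    cell$transition_frame <- NA_integer_
  } else {
    cell$static_label <- NULL
    cell$unidentified <- stats::runif(1) < cfg$unidentified_fraction
    cell$transition_frame <-
      if (cfg$condition == "starved" && !cell$unidentified)
        draw_transition_frame(cfg) else NA_integer_
  }
  cell
}

#' Generate one synthetic five-frame sequence with ground truth
#'
#' Cells are smoothed radial-perturbation blobs around drifting centroids.
#' Basal cells carry few small puncta rendered in both green and red;
#' activated cells carry more, larger puncta rendered in red only. Under the
#' fed condition no cell ever transitions; under starvation each cell's
#' transition frame is drawn from the configured normal distribution. A
#' dividing cell is replaced by two daughters (fresh track ids, parent
#' recorded) that inherit its state. Channels receive Gaussian read noise and
#' are quantized to integer counts, so identical configurations (including
#' the seed) reproduce the output bit-for-bit.
#'
#' @param config A [synth_config].
#' @return A list with elements `sequence` (a [cell_sequence]) and `truth`
#'   (a `synth_truth` list: per-frame cell table with track ids and labels,
#'   per-track table with transition frames, division events, and the planted
#'   punctum table with exact rasterized areas).
#' @export
generate_sequence <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  cfg <- config
  with_rng(cfg$seed, {
    sz <- cfg$image_size
    dm <- c(sz, sz)

    # --- initial placement with bounded retries and an overlap cap ---------
    cells <- list()
    next_track <- 1L
    sep_extra <- max(8, 6 * cfg$motion_sd)
    n_target <- cfg$n_cells
    for (i in seq_len(n_target)) {
      radius <- max(cfg$cell_radius_mean * 0.5,
                    min(cfg$cell_radius_mean * 2,
                        stats::rnorm(1, cfg$cell_radius_mean, cfg$cell_radius_sd)))
      margin <- radius * 1.4 + 3
      placed <- FALSE
      for (k in seq_len(300L)) {
        ctr <- stats::runif(2, margin, sz - margin)
        ok <- TRUE
        for (cl in cells) {
          if (sqrt(sum((ctr - cl$center)^2)) <
              radius + cl$base_radius + sep_extra) { ok <- FALSE; break }
        }
        if (ok) { placed <- TRUE; break }
      }
      if (!placed) {
        warning(sprintf("could only place %d of %d cells without overlap",
                        length(cells), n_target), call. = FALSE)
        break
      }
      cells[[length(cells) + 1L]] <- new_synth_cell(cfg, next_track, ctr, radius)
      next_track <- next_track + 1L
    }

    frames <- vector("list", 5L)
    cell_rows <- list()
    puncta_rows <- list()
    division_rows <- list()
    track_info <- stats::setNames(
      lapply(cells, function(cl)
        list(parent = cl$parent_track_id, first = 0L, last = 0L,
             transition_frame = cl$transition_frame,
             unidentified = cl$unidentified)),
      vapply(cells, function(cl) as.character(cl$track_id), character(1)))

    for (t in 0:4) {
      if (t > 0L) {
        # drift, clamped to keep blobs inside the image
        for (i in seq_along(cells)) {
          cl <- cells[[i]]
          m <- cl$base_radius * 1.4 + 3
          ctr <- cl$center + stats::rnorm(2, 0, cfg$motion_sd)
          cells[[i]]$center <- pmin(pmax(ctr, m), sz - m)
        }
        # divisions: parent retired, two daughters inherit its state
        kept <- list()
        for (cl in cells) {
          if (stats::runif(1) < cfg$division_prob) {
            axis <- stats::runif(1, 0, 2 * pi)
            off <- cl$base_radius * c(cos(axis), sin(axis))
            r_d <- cl$base_radius / sqrt(2)
            m <- r_d * 1.4 + 3
            state <- list(unidentified = cl$unidentified,
                          transition_frame = cl$transition_frame,
                          static_label = cl$static_label)
            d1 <- new_synth_cell(cfg, next_track,
                                 pmin(pmax(cl$center + off, m), sz - m),
                                 r_d, cl$track_id, state)
            d2 <- new_synth_cell(cfg, next_track + 1L,
                                 pmin(pmax(cl$center - off, m), sz - m),
                                 r_d, cl$track_id, state)
            division_rows[[length(division_rows) + 1L]] <-
              data.frame(timepoint = t, parent_track_id = cl$track_id,
                         child1_track_id = d1$track_id,
                         child2_track_id = d2$track_id)
            for (d in list(d1, d2))
              track_info[[as.character(d$track_id)]] <-
                list(parent = cl$track_id, first = t, last = t,
                     transition_frame = d$transition_frame,
                     unidentified = d$unidentified)
            kept <- c(kept, list(d1, d2))
            next_track <- next_track + 2L
          } else kept <- c(kept, list(cl))
        }
        cells <- kept
      }

      # rasterize in track order; later cells yield contested pixels
      cells <- cells[order(vapply(cells, `[[`, integer(1), "track_id"))]
      owner <- matrix(FALSE, sz, sz)
      green <- matrix(cfg$background_level, sz, sz)
      red <- matrix(cfg$background_level, sz, sz)
      trans <- matrix(cfg$background_level, sz, sz)
      recs <- list()
      for (i in seq_along(cells)) {
        cl <- cells[[i]]
        label <- cell_label_at(cl, t, cfg$condition)
        r_eff <- cl$base_radius *
          if (label == "activated") 1 else sqrt(1 + cfg$basal_area_excess)
        pert <- if (label == "activated") cfg$activated_perturbation
                else cfg$basal_perturbation
        mask <- radial_blob_mask(dm, cl$center[1L], cl$center[2L], r_eff,
                                 cl$n_vertices, pert)
        mask[owner] <- FALSE
        if (!any(mask)) {
          cy <- round(cl$center[2L]); cx <- round(cl$center[1L])
          mask[max(1L, min(sz, cy)), max(1L, min(sz, cx))] <- TRUE
          mask[owner] <- FALSE
        }
        owner <- owner | mask
        amp <- if (cl$unidentified) cfg$unidentified_intensity else cfg$cell_intensity
        green[mask] <- green[mask] + amp
        red[mask] <- red[mask] + amp
        edge <- mask & !(EBImage::erode(mask * 1, EBImage::makeBrush(3, "box")) > 0)
        trans[edge] <- trans[edge] + cfg$cell_intensity

        # puncta: basal -> green+red (yellow); activated -> red only
        if (label == "activated") {
          cnt <- sample(cfg$activated_puncta_count_range[1L]:
                          cfg$activated_puncta_count_range[2L], 1L)
          radii <- round_half_up(sample(cfg$puncta_radius_range[1L]:
                                          cfg$puncta_radius_range[2L],
                                        cnt, replace = TRUE) *
                                   cfg$activated_puncta_radius_scale)
          in_green <- FALSE
        } else {
          cnt <- sample(cfg$basal_puncta_count_range[1L]:
                          cfg$basal_puncta_count_range[2L], 1L)
          radii <- sample(cfg$puncta_radius_range[1L]:
                            cfg$puncta_radius_range[2L], cnt, replace = TRUE)
          in_green <- TRUE
        }
        pp <- place_puncta(mask, radii)
        amp_p <- if (cl$unidentified) cfg$unidentified_intensity else
          cfg$puncta_intensity
        if (nrow(pp) > 0) {
          for (j in seq_len(nrow(pp))) {
            px <- rasterize_disc(dm, pp$x[j], pp$y[j], pp$radius[j])
            red[px] <- red[px] + amp_p
            if (in_green) green[px] <- green[px] + amp_p
            puncta_rows[[length(puncta_rows) + 1L]] <-
              data.frame(timepoint = t, cell_id = i, track_id = cl$track_id,
                         x = pp$x[j], y = pp$y[j], radius = pp$radius[j],
                         area = nrow(px), in_green = in_green, in_red = TRUE)
          }
        }

        recs[[i]] <- cell_record(i, mask, mask_bbox(mask), label)
        cell_rows[[length(cell_rows) + 1L]] <-
          data.frame(timepoint = t, cell_id = i, track_id = cl$track_id,
                     parent_track_id = cl$parent_track_id, label = label,
                     centroid_x = cl$center[1L], centroid_y = cl$center[2L])
        track_info[[as.character(cl$track_id)]]$last <- t
      }

      quantize <- function(m) {
        m <- m + stats::rnorm(length(m), 0, cfg$noise_sd)
        matrix(pmin(65535, pmax(0, round(m))), sz, sz)
      }
      frames[[t + 1L]] <- annotated_frame(
        t, list(green = quantize(green), red = quantize(red),
                transmitted = quantize(trans)), recs)
    }

    tracks_df <- if (length(track_info) == 0L) NULL
    else do.call(rbind, c(lapply(names(track_info), function(id) {
      ti <- track_info[[id]]
      data.frame(track_id = as.integer(id),
                 parent_track_id = if (is.na(ti$parent)) NA_integer_ else ti$parent,
                 first_frame = ti$first, last_frame = ti$last,
                 transition_frame = if (is.null(ti$transition_frame) ||
                                        is.na(ti$transition_frame))
                   NA_integer_ else ti$transition_frame,
                 unidentified = isTRUE(ti$unidentified))
    }), list(make.row.names = FALSE)))
    if (is.null(tracks_df))
      tracks_df <- data.frame(track_id = integer(), parent_track_id = integer(),
                              first_frame = integer(), last_frame = integer(),
                              transition_frame = integer(),
                              unidentified = logical())
    tracks_df <- tracks_df[order(tracks_df$track_id), ]

    empty_cells <- data.frame(timepoint = integer(), cell_id = integer(),
                              track_id = integer(),
                              parent_track_id = integer(),
                              label = character(), centroid_x = numeric(),
                              centroid_y = numeric())
    truth <- structure(list(
      cells = if (length(cell_rows))
        do.call(rbind, c(cell_rows, list(make.row.names = FALSE)))
      else empty_cells,
      tracks = tracks_df,
      divisions = if (length(division_rows))
        do.call(rbind, c(division_rows, list(make.row.names = FALSE)))
      else data.frame(timepoint = integer(), parent_track_id = integer(),
                      child1_track_id = integer(), child2_track_id = integer()),
      puncta = if (length(puncta_rows))
        do.call(rbind, c(puncta_rows, list(make.row.names = FALSE)))
      else data.frame(timepoint = integer(), cell_id = integer(),
                      track_id = integer(), x = numeric(), y = numeric(),
                      radius = integer(), area = integer(),
                      in_green = logical(), in_red = logical()),
      config = cfg), class = "synth_truth")

    list(sequence = cell_sequence(frames, cfg$condition,
                                  sprintf("sim%d", cfg$seed)),
         truth = truth)
  })
}

#' Planted per-cell punctum truth
#'
#' The oracle for the spot-segmentation stage: for every cell at every frame,
#' the number of rendered red-channel puncta and their exact rasterized areas
#' (before noise). Basal cells' green punctum truth is identical by the
#' reporter rule; activated cells have no green puncta.
#'
#' @param truth The `truth` element returned by [generate_sequence].
#' @return Data frame with one row per (timepoint, cell): `spot_count`,
#'   `total_area`, `max_area` and a list column `spot_areas`.
#' @export
planted_spot_truth <- function(truth) {
  stopifnot(inherits(truth, "synth_truth"))
  cells <- truth$cells[, c("timepoint", "cell_id", "track_id")]
  pn <- truth$puncta[truth$puncta$in_red, ]
  out <- cells
  out$spot_count <- 0L
  out$total_area <- 0
  out$max_area <- 0
  out$spot_areas <- vector("list", nrow(out))
  for (i in seq_len(nrow(out))) {
    sel <- pn$timepoint == out$timepoint[i] & pn$cell_id == out$cell_id[i]
    areas <- pn$area[sel]
    out$spot_areas[[i]] <- areas
    out$spot_count[i] <- length(areas)
    out$total_area[i] <- sum(areas)
    out$max_area[i] <- if (length(areas)) max(areas) else 0
  }
  out
}

#' Generate a batch of single-cell masks for morphology studies
#'
#' Draws `n_per_class` basal/activated cell pairs with the configured
#' morphology contrast (basal larger by `basal_area_excess`, less circular
#' via stronger boundary perturbation), each cell rasterized on its own
#' canvas. The two cells of a pair share one base radius, so the recovered
#' between-class contrast estimates the planted one without the base-radius
#' sampling noise.
#'
#' @param n_per_class Cells per class.
#' @param config A [synth_config]; geometry fields and `seed` are used.
#' @return A list with `masks` (list of logical matrices, basal first) and
#'   `labels`.
#' @export
generate_cell_batch <- function(n_per_class, config = synth_config()) {
  cfg <- config
  with_rng(cfg$seed, {
    basal <- vector("list", n_per_class)
    activated <- vector("list", n_per_class)
    one <- function(radius, lab) {
      r_eff <- radius *
        if (lab == "activated") 1 else sqrt(1 + cfg$basal_area_excess)
      pert <- if (lab == "activated") cfg$activated_perturbation
              else cfg$basal_perturbation
      side <- ceiling(2 * r_eff * 1.6) + 8L
      nv <- sample(cfg$n_vertices_range[1L]:cfg$n_vertices_range[2L], 1L)
      radial_blob_mask(c(side, side), side / 2, side / 2, r_eff, nv, pert)
    }
    for (i in seq_len(n_per_class)) {
      radius <- max(cfg$cell_radius_mean * 0.5,
                    min(cfg$cell_radius_mean * 2,
                        stats::rnorm(1, cfg$cell_radius_mean,
                                     cfg$cell_radius_sd)))
      basal[[i]] <- one(radius, "basal")
      activated[[i]] <- one(radius, "activated")
    }
    list(masks = c(basal, activated),
         labels = rep(c("basal", "activated"), each = n_per_class))
  })
}

#' Write a generated sequence and its ground truth to disk
#'
#' Writes the sequence via [write_sequence] plus a tracks CSV
#' (`tracks.csv`: track_id, timepoint, cell_id, parent_track_id) and a truth
#' JSON (`truth.json`: transition frames and division events).
#'
#' @param sim The list returned by [generate_sequence].
#' @param out_dir Output directory.
#' @return Invisibly, `out_dir`.
#' @export
write_simulation <- function(sim, out_dir) {
  write_sequence(sim$sequence, out_dir)
  tr <- sim$truth$cells[, c("track_id", "timepoint", "cell_id",
                            "parent_track_id")]
  utils::write.csv(tr, file.path(out_dir, "tracks.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(tracks = sim$truth$tracks, divisions = sim$truth$divisions),
    file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
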