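# Embedding, association cost, Hungarian assignment, lifecycle and
# tracking-quality metrics.

test_that("the reference embedding is deterministic and gain-robust", {
  f <- build_test_frame()
  cl <- f$cells[[1]]
  crop <- crop_cell(f$channels, cl$box, 2)
  mcrop <- crop_cell(list(m = cl$mask), cl$box, 2)$m
  masked <- apply_mask(crop, mcrop)
  e1 <- embed_cell(masked, mcrop)
  e2 <- embed_cell(masked, mcrop)
  expect_identical(e1, e2)
  expect_equal(sum(e1^2), 1)
  # doubled uniform gain barely moves the descriptor
  doubled <- lapply(masked, function(m) m * 2)
  cos_gain <- sum(e1 * embed_cell(doubled, mcrop))
  expect_gte(cos_gain, 0.9)
  # a cell with a very different punctum pattern is farther than a gain
  # change of the same cell
  other <- masked
  other$red[mcrop] <- 200
  other$red[disc_mask(nrow(mcrop), 8, 8, 4)[seq_len(nrow(mcrop)),
                                            seq_len(ncol(mcrop))] & mcrop] <- 60000
  e3 <- embed_cell(other, mcrop)
  expect_lt(sum(e1 * e3), cos_gain)
})

test_that("cost matrix entries follow the documented formula", {
  tr <- list(track_id = 1L, status = "active",
             last_centroid = c(x = 10, y = 10),
             last_box = bbox(5, 5, 15, 15), last_feature = c(1, 0, 0))
  det <- make_det(5, 5, 15, 15, 1)
  C <- build_cost_matrix(list(tr), list(det), list(c(1, 0, 0)),
                         tracker_config(), gate = 50)
  expect_equal(C[1, 1], 0)
  # inactive candidates pay the re-identification surcharge
  tr$status <- "inactive"
  C2 <- build_cost_matrix(list(tr), list(det), list(c(1, 0, 0)),
                          tracker_config(), gate = 50)
  expect_equal(C2[1, 1], 0.1)
  # beyond the gate: forbidden
  far <- make_det(200, 200, 210, 210, 1)
  C3 <- build_cost_matrix(list(tr), list(far), list(c(1, 0, 0)),
                          tracker_config(), gate = 50)
  expect_identical(C3[1, 1], Inf)
  # randomized entries against a direct recomputation
  set.seed(33)
  cfg <- tracker_config(0.5, 0.3, 0.2)
  for (k in 1:20) {
    tr <- list(track_id = 1L, status = sample(c("active", "inactive"), 1),
               last_centroid = c(x = runif(1, 0, 60), y = runif(1, 0, 60)),
               last_box = bbox(0, 0, runif(1, 5, 20), runif(1, 5, 20)),
               last_feature = rnorm(5))
    det <- make_det(runif(1, 0, 10), runif(1, 0, 10),
                    runif(1, 12, 30), runif(1, 12, 30), 1)
    fv <- rnorm(5)
    gate <- 120
    got <- build_cost_matrix(list(tr), list(det), list(fv), cfg, gate)[1, 1]
    ctr <- c((det$box[["x0"]] + det$box[["x1"]]) / 2,
             (det$box[["y0"]] + det$box[["y1"]]) / 2)
    d <- sqrt(sum((unname(tr$last_centroid) - ctr)^2))
    cosv <- sum(tr$last_feature * fv) /
      sqrt(sum(tr$last_feature^2) * sum(fv^2))
    want <- 0.5 * d / gate + 0.3 * (1 - cosv) / 2 +
      0.2 * (1 - box_iou(tr$last_box, det$box)) +
      if (tr$status == "inactive") 0.1 else 0
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("hungarian equals the exhaustive assignment optimum", {
  expect_equal(hungarian(matrix(0, 1, 1))$pairs,
               cbind(row = 1L, col = 1L))
  h <- hungarian(matrix(c(1, 2, 2, 1), 2, byrow = TRUE))
  expect_equal(h$total, 2)
  expect_equal(h$pairs[, "col"], c(1L, 2L))
  expect_equal(nrow(hungarian(matrix(Inf, 3, 3))$pairs), 0L)
  set.seed(99)
  for (k in 1:100) {
    nr <- sample(1:6, 1); nc <- sample(1:6, 1)
    C <- matrix(round(runif(nr * nc, 0, 10), 3), nr, nc)
    C[runif(nr * nc) < 0.25] <- Inf
    got <- hungarian(C)
    want <- brute_force_assignment(C)
    expect_equal(nrow(got$pairs), want$card)
    expect_equal(got$total, want$total, tolerance = 1e-9)
  }
})

test_that("a stationary cell yields one five-link active track", {
  dets <- lapply(0:4, function(t) list(make_det(20, 20, 40, 40, 1,
                                                cell_id = 1L)))
  feats <- lapply(dets, function(fr) lapply(fr, function(d) c(1, 0)))
  tracks <- track_sequence(dets, feats, tracker_config(gate_radius = 50))
  expect_equal(length(tracks), 1L)
  expect_equal(nrow(tracks[[1]]$links), 5L)
  expect_equal(tracks[[1]]$status, "active")
  expect_equal(tracks[[1]]$links$timepoint, 0:4)
  # determinism
  tracks2 <- track_sequence(dets, feats, tracker_config(gate_radius = 50))
  expect_identical(tracks, tracks2)
  expect_error(track_sequence(list(), list()), "empty")
})

test_that("a disappearing cell is re-identified from the inactive pool", {
  pos <- list(c(20, 20), c(21, 20), NULL, c(20, 21), c(20, 20))
  dets <- lapply(pos, function(p) if (is.null(p)) list()
                 else list(make_det(p[1], p[2], p[1] + 20, p[2] + 20, 1,
                                    cell_id = 1L)))
  feats <- lapply(dets, function(fr) lapply(fr, function(d) c(0.3, 0.7)))
  tracks <- track_sequence(dets, feats, tracker_config(gate_radius = 60))
  expect_equal(length(tracks), 1L)           # same identity resumes
  expect_equal(tracks[[1]]$links$timepoint, c(0, 1, 3, 4))
})

test_that("an inactive track keeps its history and timepoints increase", {
  dets <- list(list(make_det(10, 10, 30, 30, 1, 1L),
                    make_det(60, 60, 80, 80, 1, 2L)),
               list(make_det(10, 10, 30, 30, 1, 1L)),
               list(make_det(10, 10, 30, 30, 1, 1L)))
  feats <- lapply(dets, function(fr) lapply(fr, function(d) c(1, 1)))
  tracks <- track_sequence(dets, feats, tracker_config(gate_radius = 40))
  st <- vapply(tracks, `[[`, character(1), "status")
  lost <- tracks[[which(st == "inactive")]]
  expect_equal(nrow(lost$links), 1L)         # history preserved
  for (tr in tracks) expect_true(all(diff(tr$links$timepoint) > 0))
})

test_that("division children link to the matched parent by box overlap", {
  # one cell splits at t2 into two overlapping daughters
  dets <- list(list(make_det(20, 20, 44, 44, 1, 1L)),
               list(make_det(21, 20, 45, 44, 1, 1L)),
               list(make_det(12, 14, 32, 34, 1, 1L),
                    make_det(32, 28, 52, 48, 1, 2L)))
  feats <- lapply(dets, function(fr) lapply(fr, function(d) c(1, 0)))
  tracks <- track_sequence(dets, feats, tracker_config(gate_radius = 60))
  expect_equal(length(tracks), 2L)
  child <- tracks[[2]]
  expect_equal(child$parent_track_id, tracks[[1]]$track_id)

  # generator sequence with divisions: children carry parent links and the
  # lineage-aware metrics stay clean
  sim <- generate_sequence(synth_config(seed = 9, division_prob = 0.08))
  expect_gt(nrow(sim$truth$divisions), 0)
  td <- truth_detections(sim)
  tracks2 <- track_sequence(td$detections, td$features)
  tt <- tracks_table(tracks2)
  first <- tt[!duplicated(tt$track_id), ]
  expect_gt(sum(!is.na(first$parent_track_id)), 0)
  tm <- tracking_metrics(tracks2, sim$truth)
  expect_equal(tm$identity_switches, 0L)
  expect_equal(tm$fragmentation, 0L)
})

test_that("with zero feature weight the tracker is nearest-neighbour", {
  set.seed(14)
  pts <- matrix(runif(12, 0, 200), 6, 2)
  mk <- function(p, id) make_det(p[1], p[2], p[1] + 10, p[2] + 10, 1, id)
  d0 <- lapply(1:6, function(i) mk(pts[i, ], i))
  drift <- pts + matrix(runif(12, -3, 3), 6, 2)
  d1 <- lapply(1:6, function(i) mk(drift[i, ], i))
  feats <- lapply(1:6, function(i) rnorm(4))
  tracks <- track_sequence(list(d0, d1), list(feats, feats),
                           tracker_config(0.8, 0, 0.2, gate_radius = 40))
  # each track's two links reference the same underlying cell
  for (tr in tracks) {
    expect_equal(nrow(tr$links), 2L)
    expect_equal(tr$links$cell_id[1], tr$links$cell_id[2])
  }
})

test_that("appearance features rescue crossing cells that swap positions", {
  fB <- c(1, 0); fC <- c(-1, 0)
  d0 <- list(make_det(10, 10, 30, 30, 1, 1L), make_det(60, 60, 80, 80, 1, 2L))
  d1 <- list(make_det(60, 60, 80, 80, 1, 3L), make_det(10, 10, 30, 30, 1, 4L))
  feats <- list(list(fB, fC), list(fB, fC))
  truth <- data.frame(timepoint = c(0, 0, 1, 1), cell_id = 1:4,
                      track_id = c(1, 2, 1, 2))
  with_feat <- tracking_metrics(
    track_sequence(list(d0, d1), feats,
                   tracker_config(0.3, 0.6, 0.1, gate_radius = 100)), truth)
  without <- tracking_metrics(
    track_sequence(list(d0, d1), feats,
                   tracker_config(0.8, 0, 0.2, gate_radius = 100)), truth)
  expect_equal(with_feat$identity_switches, 0L)
  expect_equal(without$identity_switches, 2L)
})

test_that("per-step conservation: every detection is accounted for", {
  sim <- generate_sequence(synth_config(seed = 17, division_prob = 0.1))
  td <- truth_detections(sim)
  state <- tracker_init(td$detections[[1]], td$features[[1]])
  for (t in 2:5) {
    links_before <- sum(vapply(state$tracks, function(tr) nrow(tr$links),
                               integer(1)))
    state <- tracker_step(state, td$detections[[t]], td$features[[t]])
    links_after <- sum(vapply(state$tracks, function(tr) nrow(tr$links),
                              integer(1)))
    # each detection lands in exactly one track (extension, child, or new)
    expect_equal(links_after - links_before, length(td$detections[[t]]))
    for (tr in state$tracks) {
      expect_false(any(duplicated(tr$links$timepoint)))
      expect_true(all(diff(tr$links$timepoint) > 0))
    }
  }
})

test_that("tracking metrics count splits and swaps as defined", {
  # perfect tracking
  truth <- data.frame(timepoint = rep(0:4, 2), cell_id = rep(1:2, each = 5),
                      track_id = rep(1:2, each = 5))
  mk_track <- function(id, tps, cells) list(
    track_id = id, status = "active",
    links = data.frame(timepoint = tps, det_index = seq_along(tps),
                       cell_id = cells))
  perfect <- list(mk_track(1L, 0:4, rep(1L, 5)), mk_track(2L, 0:4, rep(2L, 5)))
  m <- tracking_metrics(perfect, truth)
  expect_equal(m$identity_switches, 0L)
  expect_equal(m$fragmentation, 0L)
  expect_equal(m$track_purity, 1)
  # one truth track split across two predicted tracks: fragmentation 1
  split <- list(mk_track(1L, 0:2, rep(1L, 3)), mk_track(3L, 3:4, rep(1L, 2)),
                mk_track(2L, 0:4, rep(2L, 5)))
  expect_equal(tracking_metrics(split, truth)$fragmentation, 1L)
  # two predicted tracks swap underlying cells at t2: two switches
  swapped <- list(mk_track(1L, 0:4, c(1L, 1L, 2L, 2L, 2L)),
                  mk_track(2L, 0:4, c(2L, 2L, 1L, 1L, 1L)))
  m2 <- tracking_metrics(swapped, truth)
  expect_equal(m2$identity_switches, 2L)
  expect_error(tracking_metrics(
    list(mk_track(1L, 0:1, c(9L, 9L))), truth), "absent")
})
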