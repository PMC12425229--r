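# Detection/segmentation metrology and the classical reference detector.

test_that("box IoU follows half-open pixel geometry", {
  expect_equal(box_iou(bbox(0, 0, 10, 10), bbox(0, 0, 10, 10)), 1)
  expect_equal(box_iou(bbox(0, 0, 5, 5), bbox(20, 20, 30, 30)), 0)
  expect_equal(box_iou(bbox(0, 0, 2, 1), bbox(1, 0, 3, 1)), 1 / 3)
})

test_that("matching is greedy in confidence with one-to-one pairing", {
  gt <- list(bbox(0, 0, 10, 10))
  dets <- list(make_det(0, 0, 10, 10, 0.8), make_det(1, 0, 11, 10, 0.9))
  m <- match_detections(dets, gt, 0.5)
  expect_equal(nrow(m$pairs), 1L)
  expect_equal(m$pairs$det, 2L)      # higher confidence wins the only gt
  expect_equal(m$unmatched_dets, 1L)

  # randomized instances agree with an independent greedy oracle
  set.seed(42)
  for (k in 1:60) {
    nd <- sample(1:6, 1); ng <- sample(1:5, 1)
    db <- t(sapply(seq_len(nd), function(i) {
      x0 <- runif(1, 0, 30); y0 <- runif(1, 0, 30)
      c(x0, y0, x0 + runif(1, 4, 15), y0 + runif(1, 4, 15))
    }))
    gb <- t(sapply(seq_len(ng), function(i) {
      x0 <- runif(1, 0, 30); y0 <- runif(1, 0, 30)
      c(x0, y0, x0 + runif(1, 4, 15), y0 + runif(1, 4, 15))
    }))
    confs <- round(runif(nd), 3)
    dets <- lapply(seq_len(nd), function(i)
      make_det(db[i, 1], db[i, 2], db[i, 3], db[i, 4], confs[i]))
    gts <- lapply(seq_len(ng), function(i)
      bbox(gb[i, 1], gb[i, 2], gb[i, 3], gb[i, 4]))
    got <- match_detections(dets, gts, 0.3)$pairs
    want <- match_oracle(db, confs, gb, 0.3)
    if (is.null(want)) {
      expect_equal(nrow(got), 0L)
    } else {
      want <- want[order(want[, 1]), , drop = FALSE]
      expect_equal(got$det, as.integer(want[, 1]))
      expect_equal(got$gt, as.integer(want[, 2]))
    }
  }
})

test_that("average precision reproduces the hand-enumerated envelope cases", {
  gt <- list(list(bbox(0, 0, 10, 10)))
  hit <- function(conf) make_det(0, 0, 10, 10, conf)
  miss <- function(conf) make_det(50, 50, 60, 60, conf)
  # false positive ranked above the true positive: AP 0.5
  expect_equal(average_precision(list(list(miss(0.95), hit(0.90))), gt, 0.5),
               0.5)
  # true positive ranked first: the envelope is 1 everywhere
  expect_equal(average_precision(list(list(hit(0.95), miss(0.90))), gt, 0.5),
               1.0)
  # every gt hit once, no false positives
  expect_equal(average_precision(list(list(hit(1))), gt, 0.5), 1.0)
  expect_error(average_precision(list(list(hit(1))), list(list()), 0.5),
               "zero ground truths")
})

test_that("average precision matches an independent oracle on random scenes", {
  set.seed(7)
  for (k in 1:100) {
    n_img <- sample(1:3, 1)
    db <- cf <- gb <- list()
    for (im in seq_len(n_img)) {
      ng <- sample(1:4, 1); nd <- sample(0:6, 1)
      gb[[im]] <- t(sapply(seq_len(ng), function(i) {
        x0 <- runif(1, 0, 40); y0 <- runif(1, 0, 40)
        c(x0, y0, x0 + runif(1, 5, 15), y0 + runif(1, 5, 15))
      }))
      db[[im]] <- if (nd > 0) t(sapply(seq_len(nd), function(i) {
        if (runif(1) < 0.6 && i <= ng) gb[[im]][i, ] + runif(4, -3, 3)
        else { x0 <- runif(1, 0, 40); y0 <- runif(1, 0, 40)
               c(x0, y0, x0 + runif(1, 5, 15), y0 + runif(1, 5, 15)) }
      })) else matrix(numeric(), 0, 4)
      cf[[im]] <- round(runif(nd), 3)
    }
    dets <- lapply(seq_len(n_img), function(im)
      lapply(seq_len(nrow(db[[im]])), function(i)
        make_det(db[[im]][i, 1], db[[im]][i, 2],
                 pmax(db[[im]][i, 3], db[[im]][i, 1] + 1),
                 pmax(db[[im]][i, 4], db[[im]][i, 2] + 1), cf[[im]][i])))
    db <- lapply(seq_len(n_img), function(im) {
      m <- db[[im]]
      if (nrow(m)) { m[, 3] <- pmax(m[, 3], m[, 1] + 1)
                     m[, 4] <- pmax(m[, 4], m[, 2] + 1) }
      m
    })
    gts <- lapply(gb, function(m) lapply(seq_len(nrow(m)), function(i)
      bbox(m[i, 1], m[i, 2], m[i, 3], m[i, 4])))
    expect_equal(average_precision(dets, gts, 0.5),
                 ap_oracle(db, cf, gb, 0.5), tolerance = 1e-12)
  }
})

test_that("AP is invariant to image relabeling and monotone in the threshold", {
  set.seed(11)
  gb <- t(sapply(1:4, function(i) {
    x0 <- runif(1, 0, 40); y0 <- runif(1, 0, 40)
    c(x0, y0, x0 + 10, y0 + 10)
  }))
  gts <- lapply(seq_len(4), function(i) bbox(gb[i,1], gb[i,2], gb[i,3], gb[i,4]))
  dets <- c(lapply(1:4, function(i)
    make_det(gb[i,1]+2, gb[i,2]+2, gb[i,3]+2, gb[i,4]+2, runif(1))),
    list(make_det(80, 80, 90, 90, 0.5)))
  ap_one <- average_precision(list(dets), list(gts), 0.5)
  # split the same scene over two images
  ap_two <- average_precision(list(dets[1:2], dets[3:5]),
                              list(gts[1:2], gts[3:4]), 0.5)
  expect_equal(ap_one, ap_two)
  # monotone transform of confidences preserves AP
  dets2 <- lapply(dets, function(d) { d$confidence <- d$confidence^3; d })
  expect_equal(average_precision(list(dets2), list(gts), 0.5), ap_one)
  # AP non-increasing in the IoU threshold
  aps <- sapply(seq(0.5, 0.95, 0.05), function(th)
    average_precision(list(dets), list(gts), th))
  expect_true(all(diff(aps) <= 1e-12))
  expect_equal(mean_average_precision(list(dets), list(gts)), mean(aps))
})

test_that("pixel metrics equal direct confusion counts", {
  m <- disc_mask(50, 25, 25, 10)
  expect_equal(unlist(pixel_metrics(m, m)),
               c(iou = 1, f1 = 1, precision = 1, recall = 1, accuracy = 1))
  # disjoint 10-px masks in a 100-px image
  p <- matrix(FALSE, 10, 10); p[1:10] <- TRUE
  t <- matrix(FALSE, 10, 10); t[51:60] <- TRUE
  pm <- pixel_metrics(p, t)
  expect_equal(pm$iou, 0); expect_equal(pm$precision, 0)
  expect_equal(pm$recall, 0); expect_equal(pm$accuracy, 0.8)
  # dilation ring: metrics from raw pixel counts
  pred <- EBImage::dilate(m * 1, EBImage::makeBrush(3, "box")) > 0
  cnt <- pixel_oracle(pred, m)
  pm2 <- pixel_metrics(pred, m)
  expect_equal(pm2$iou, cnt$tp / (cnt$tp + cnt$fp + cnt$fn))
  expect_equal(pm2$precision, cnt$tp / (cnt$tp + cnt$fp))
  expect_equal(pm2$recall, 1)
  expect_equal(pm2$accuracy, (cnt$tp + cnt$tn) / 2500)
  # empty-vs-empty agreement and IoU <= F1 in general
  z <- matrix(FALSE, 5, 5)
  expect_equal(pixel_metrics(z, z)$iou, 1)
  set.seed(3)
  for (k in 1:50) {
    a <- matrix(runif(100) > 0.5, 10, 10)
    b <- matrix(runif(100) > 0.5, 10, 10)
    pm3 <- pixel_metrics(a, b)
    expect_lte(pm3$iou, pm3$f1 + 1e-12)
  }
})

test_that("the reference detector finds well-separated synthetic cells", {
  sim <- generate_sequence(synth_config(seed = 1, n_cells = 10,
                                        division_prob = 0))
  for (f in sim$sequence$frames) {
    dets <- filter_by_confidence(reference_detect(f), 0.65)
    gt <- lapply(f$cells, `[[`, "box")
    m <- match_detections(dets, gt, 0.5)
    expect_equal(nrow(m$pairs), length(gt))  # recall 1 at IoU 0.5
  }
  # blank frame: nothing detected
  blank <- list(green = matrix(200, 64, 64), red = matrix(200, 64, 64))
  expect_equal(length(reference_detect(channels = blank)), 0L)
})

test_that("the watershed splits two touching cells into two detections", {
  side <- 128
  m1 <- disc_mask(side, 50, 64, 18)
  m2 <- disc_mask(side, 85, 64, 18)
  img <- matrix(200, side, side); img[m1 | m2] <- 800
  dets <- reference_detect(channels = list(green = img, red = img))
  expect_equal(length(dets), 2L)
})

test_that("crop and mask isolate a cell against a black background", {
  f <- build_test_frame()
  cl <- f$cells[[1]]
  crop <- crop_cell(f$channels, cl$box, pad = 0)
  expect_equal(dim(crop$green),
               c(cl$box[["y1"]] - cl$box[["y0"]],
                 cl$box[["x1"]] - cl$box[["x0"]]))
  mcrop <- crop_cell(list(m = cl$mask), cl$box, pad = 0)$m
  masked <- apply_mask(crop, mcrop)
  expect_equal(sum(masked$green[!mcrop]), 0)
  # full mask is the identity
  full <- apply_mask(crop, matrix(TRUE, nrow(mcrop), ncol(mcrop)))
  expect_identical(full$green, unclass(crop$green))
  expect_error(crop_cell(f$channels, bbox(60, 60, 70, 70)), "outside")
})

test_that("confidence filtering keeps detections at or above the cut", {
  dets <- list(make_det(0, 0, 5, 5, 0.9), make_det(0, 0, 5, 5, 0.64))
  expect_equal(length(filter_by_confidence(dets, 0.65)), 1L)
  expect_equal(length(filter_by_confidence(dets, 0)), 2L)
  expect_equal(length(filter_by_confidence(dets, 1)), 0L)
})
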