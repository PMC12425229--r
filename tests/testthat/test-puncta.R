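# Spot segmentation, normalization, the activation threshold, morphology,
# and classification metrics.

test_that("spot segmentation recovers planted puncta exactly without noise", {
  sim <- generate_sequence(synth_config(seed = 5, noise_sd = 0))
  ps <- planted_spot_truth(sim$truth)
  f <- sim$sequence$frames[[1]]
  for (cl in f$cells) {
    sp <- segment_spots(f$channels$red, cl$mask, cell_id = cl$cell_id)
    want <- ps[ps$timepoint == 0 & ps$cell_id == cl$cell_id, ]
    expect_equal(sp$spot_count, want$spot_count)
    expect_equal(sp$total_area, want$total_area)
    expect_equal(sort(sp$spot_areas), sort(want$spot_areas[[1]]))
  }
})

test_that("uniform signal yields zero spots and tiny spots are filtered", {
  mask <- disc_mask(64, 32, 32, 20)
  flat <- matrix(500, 64, 64)
  sp <- segment_spots(flat, mask)
  expect_equal(sp$spot_count, 0L)
  expect_true(sp$no_spots)
  # a 2-pixel speck falls below the default 4-px minimum area
  img <- flat; img[32, 32:33] <- 9000
  sp2 <- segment_spots(img, mask)
  expect_equal(sp2$spot_count, 0L)
  # a radius-3 disc survives and is measured exactly
  img3 <- flat
  d <- disc_mask(64, 30, 30, 3)
  img3[d] <- 9000
  sp3 <- segment_spots(img3, mask)
  expect_equal(sp3$spot_count, 1L)
  expect_equal(sp3$max_area, sum(d))
  expect_error(segment_spots(flat, matrix(FALSE, 64, 64)), "empty")
})

test_that("replicate normalization divides by the median then takes log10", {
  expect_equal(normalize_and_log(c(5, 5, 5), rep("a", 3)), c(0, 0, 0))
  expect_equal(normalize_and_log(c(1, 10, 100), rep("a", 3)), c(-1, 0, 1))
  # scaling any replicate leaves its transformed values unchanged
  v <- c(1, 3, 9, 2, 6, 18)
  r <- c("a", "a", "a", "b", "b", "b")
  expect_equal(normalize_and_log(v, r),
               normalize_and_log(v * c(1, 1, 1, 7, 7, 7), r))
  expect_equal(normalize_and_log(v, r)[1:3], normalize_and_log(v, r)[4:6])
  expect_error(normalize_and_log(c(0, 1), c("a", "a")), "> 0")
})

test_that("the percentile threshold is the type-7 order statistic", {
  expect_equal(activation_threshold(1:20, 95), 19.05)
  expect_equal(activation_threshold(rep(3.2, 10), 95), 3.2)
  set.seed(8)
  x <- rnorm(1000)
  for (p in c(50, 90, 95, 99))
    expect_equal(activation_threshold(x, p), quantile_oracle(x, p / 100))
  expect_error(activation_threshold(numeric(), 95), "calibration")
  expect_error(activation_threshold(1, 95), "calibration")
})

test_that("threshold classification is self-consistent on its calibration set", {
  rec <- data.frame(cell_id = 1:6, feature = c(-1, 0, 0.5, 1, 1.5, 2))
  out <- classify_by_threshold(rec, 2)
  expect_true(all(out$label == "basal"))
  # no-spot cells are excluded and reported
  rec$no_spots <- c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE)
  out2 <- classify_by_threshold(rec, 0.4)
  expect_equal(attr(out2, "excluded"), 2L)
  expect_equal(sum(out2$label == "activated"), 4)
  # scoring any calibration set against its own 95th percentile marks at
  # most ceiling(0.05 n) cells activated
  set.seed(21)
  for (k in 1:50) {
    n <- sample(10:200, 1)
    v <- switch(sample(3, 1), rnorm(n), rexp(n), sample(1:20, n, TRUE))
    thr <- activation_threshold(v, 95)
    res <- classify_by_threshold(data.frame(cell_id = seq_len(n),
                                            feature = v), thr)
    expect_lte(sum(res$label == "activated"), ceiling(0.05 * n))
  }
})

test_that("morphology measures area, perimeter and circularity", {
  sq <- matrix(FALSE, 120, 120); sq[11:110, 11:110] <- TRUE
  m <- cell_morphology(sq, estimator = "boundary")
  expect_equal(m$area, 10000)
  expect_equal(m$perimeter, 400)
  expect_equal(m$circularity, pi / 4, tolerance = 1e-12)
  d <- disc_mask(121, 61, 61, 50)
  mc <- cell_morphology(d)
  expect_equal(mc$area, sum(d))
  expect_gt(mc$circularity, 0.95)
  expect_lt(mc$circularity, 1.05)
  # scale consistency: area grows as radius^2
  d2 <- disc_mask(61, 31, 31, 25)
  expect_equal(mc$area / cell_morphology(d2)$area, 4, tolerance = 0.01)
  # multi-component mask: largest is measured, with a warning
  two <- d2; two[1:3, 1:3] <- TRUE
  expect_warning(m2 <- cell_morphology(two), "components")
  expect_equal(m2$area, sum(d2))
  expect_error(cell_morphology(matrix(FALSE, 4, 4)), "empty")
})

test_that("class comparison recovers percent differences and Welch t", {
  df <- data.frame(area = c(10, 12, 14, 10, 12, 14),
                   circularity = rep(0.9, 6))
  lab <- rep(c("basal", "activated"), each = 3)
  cc <- compare_classes(df, lab)
  expect_equal(cc$percent_diff_area, 0)
  expect_equal(cc$t_area, 0)
  expect_equal(cc$p_area, 1)
  # areas {1,2,3} vs {4,5,6}: means 2 and 5, variances 1, se = sqrt(2/3)
  df2 <- data.frame(area = c(1, 2, 3, 4, 5, 6), circularity = rep(1, 6))
  cc2 <- compare_classes(df2, lab)
  expect_equal(cc2$t_area, -3 / sqrt(2 / 3), tolerance = 1e-6)
  expect_equal(cc2$percent_diff_area, -60)
  # swapping the class labels negates t and maps the percent difference to
  # its reciprocal-form counterpart
  cc3 <- compare_classes(df2, rev(lab))
  expect_equal(cc3$t_area, -cc2$t_area)
  expect_equal((1 + cc2$percent_diff_area / 100) *
                 (1 + cc3$percent_diff_area / 100), 1)
  expect_error(compare_classes(df2[1:3, ], lab[1:3]), "at least 2")
})

test_that("classification metrics match closed forms and the MCC oracle", {
  cm <- diag(c(5L, 7L, 3L))
  m <- classification_metrics(cm)
  expect_equal(unlist(m),
               c(accuracy = 1, precision = 1, recall = 1, f1 = 1, mcc = 1))
  # binary TP=45 FN=5 FP=5 TN=45: MCC = 2000/2500
  cm2 <- matrix(c(45, 5, 5, 45), 2, byrow = TRUE)
  m2 <- classification_metrics(cm2)
  expect_equal(m2$mcc, 0.8)
  expect_equal(m2$accuracy, 0.9)
  # random 3x3 matrices agree with the covariance-form oracle
  set.seed(5)
  for (k in 1:100) {
    cm3 <- matrix(sample(0:20, 9, TRUE), 3)
    if (sum(cm3) == 0) next
    m3 <- classification_metrics(cm3)
    expect_equal(m3$mcc, mcc_oracle(cm3), tolerance = 1e-10)
    expect_gte(m3$mcc, -1); expect_lte(m3$mcc, 1)
    # simultaneous permutation of truth and prediction classes
    p <- sample(3)
    expect_equal(classification_metrics(cm3[p, p])$mcc, m3$mcc)
  }
  # a class absent from both truth and prediction is excluded with a warning
  cm4 <- matrix(0L, 3, 3); cm4[1, 1] <- 5L; cm4[2, 2] <- 5L
  expect_warning(m4 <- classification_metrics(cm4), "absent")
  expect_equal(m4$precision, 1)
})

test_that("confusion matrices are truth-by-prediction in fixed class order", {
  cm <- confusion_matrix(c("basal", "basal", "activated"),
                         c("basal", "activated", "activated"),
                         classes = c("basal", "activated"))
  expect_equal(as.vector(cm), c(1L, 0L, 1L, 1L))
  expect_equal(sum(cm), 3L)
})
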