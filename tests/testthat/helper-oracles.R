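# Independent oracles and small constructors used across the suite. These
# deliberately re-derive results from first principles (brute force,
# enumeration, direct formulas) and share no code path with the package.

# exhaustive assignment: maximal cardinality avoiding Inf, then minimum cost
brute_force_assignment <- function(cost) {
  nr <- nrow(cost); nc <- ncol(cost)
  best <- list(card = -1L, total = Inf)
  rec <- function(r, used, card, total) {
    if (r > nr) {
      if (card > best$card || (card == best$card && total < best$total))
        best <<- list(card = card, total = total)
      return()
    }
    rec(r + 1L, used, card, total)
    for (j in seq_len(nc)) if (!used[j] && is.finite(cost[r, j]))
      rec(r + 1L, replace(used, j, TRUE), card + 1L, total + cost[r, j])
  }
  rec(1L, rep(FALSE, nc), 0L, 0)
  best
}

iou_oracle <- function(a, b) {
  ix <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  iy <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- ix * iy
  aa <- (a[3] - a[1]) * (a[4] - a[2]); ab <- (b[3] - b[1]) * (b[4] - b[2])
  if (aa + ab - inter <= 0) 0 else inter / (aa + ab - inter)
}

# greedy confidence-ordered matching, written independently over plain arrays
match_oracle <- function(det_boxes, confs, gt_boxes, thresh) {
  ord <- order(-confs, seq_along(confs))
  taken <- rep(FALSE, nrow(gt_boxes))
  out <- NULL
  for (d in ord) {
    best <- 0; bi <- 0L
    for (g in seq_len(nrow(gt_boxes))) {
      if (taken[g]) next
      v <- iou_oracle(det_boxes[d, ], gt_boxes[g, ])
      if (v > best) { best <- v; bi <- g }
    }
    if (bi > 0L && best >= thresh) {
      taken[bi] <- TRUE
      out <- rbind(out, c(d, bi, best))
    }
  }
  out
}

# independent AP: flatten, greedy-match per image, raw 101-point envelope
ap_oracle <- function(det_boxes_list, confs_list, gt_boxes_list, thresh) {
  n_gt <- sum(vapply(gt_boxes_list, nrow, integer(1)))
  rows <- NULL
  for (im in seq_along(det_boxes_list)) {
    db <- det_boxes_list[[im]]
    if (is.null(db) || nrow(db) == 0) next
    rows <- rbind(rows, cbind(im, seq_len(nrow(db)), confs_list[[im]]))
  }
  if (is.null(rows)) return(0)
  rows <- rows[order(-rows[, 3], rows[, 1], rows[, 2]), , drop = FALSE]
  taken <- lapply(gt_boxes_list, function(g) rep(FALSE, nrow(g)))
  tp <- logical(nrow(rows))
  for (k in seq_len(nrow(rows))) {
    im <- rows[k, 1]; d <- rows[k, 2]
    gb <- gt_boxes_list[[im]]
    if (nrow(gb) == 0) next
    best <- -1; bi <- 0L
    for (g in seq_len(nrow(gb))) {
      if (taken[[im]][g]) next
      v <- iou_oracle(det_boxes_list[[im]][d, ], gb[g, ])
      if (v > best) { best <- v; bi <- g }
    }
    if (bi > 0L && best >= thresh) { taken[[im]][bi] <- TRUE; tp[k] <- TRUE }
  }
  prec <- cumsum(tp) / seq_along(tp)
  rec <- cumsum(tp) / n_gt
  mean(sapply(0:100 / 100, function(r) {
    sel <- rec >= r - 1e-12
    if (!any(sel)) 0 else max(prec[sel])
  }))
}

# multiclass MCC from first principles: one-hot expansion and summed
# covariances
mcc_oracle <- function(cm) {
  K <- nrow(cm); n <- sum(cm)
  truth <- rep(rep(seq_len(K), K), times = as.vector(t(cm)))
  pred <- rep(rep(seq_len(K), each = K), times = as.vector(t(cm)))
  X <- sapply(seq_len(K), function(k) as.numeric(truth == k))
  Y <- sapply(seq_len(K), function(k) as.numeric(pred == k))
  covs <- function(A, B) sum(sapply(seq_len(K), function(k)
    mean(A[, k] * B[, k]) - mean(A[, k]) * mean(B[, k])))
  den <- sqrt(covs(X, X) * covs(Y, Y))
  if (den == 0) 0 else covs(X, Y) / den
}

# direct order-statistic percentile (linear interpolation, h = (n-1)p)
quantile_oracle <- function(x, p) {
  s <- sort(x)
  h <- (length(s) - 1) * p
  lo <- floor(h)
  s[lo + 1] + (h - lo) * (s[min(lo + 2, length(s))] - s[lo + 1])
}

pixel_oracle <- function(pred, truth) {
  tp <- sum(pred & truth); fp <- sum(pred & !truth)
  fn <- sum(!pred & truth); tn <- sum(!pred & !truth)
  list(tp = tp, fp = fp, fn = fn, tn = tn)
}

disc_mask <- function(side, cx, cy, r) {
  xs <- seq_len(side)
  outer((xs - cy)^2, (xs - cx)^2, "+") <= r^2
}

make_det <- function(x0, y0, x1, y1, conf = 1, cell_id = NULL, mask = NULL) {
  d <- detection(bbox(x0, y0, x1, y1), conf, mask)
  if (!is.null(cell_id)) d$cell_id <- cell_id
  d
}

# small fully-annotated frame built in code for IO tests
build_test_frame <- function(timepoint = 0L, n_cells = 2L, side = 64L,
                             seed = 7L) {
  set.seed(seed)
  cells <- list()
  centers <- list(c(18, 18), c(46, 44), c(20, 46))[seq_len(n_cells)]
  green <- matrix(200, side, side)
  red <- matrix(210, side, side)
  trans <- matrix(190, side, side)
  for (i in seq_along(centers)) {
    m <- disc_mask(side, centers[[i]][1], centers[[i]][2], 8)
    green[m] <- 900 + i
    red[m] <- 950 + i
    cells[[i]] <- cell_record(i, m,
                              label = c("basal", "activated",
                                        "unidentified")[i %% 3 + 1])
  }
  annotated_frame(timepoint,
                  list(green = green, red = red, transmitted = trans), cells)
}
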