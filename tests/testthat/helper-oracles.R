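# Independent brute-force reference implementations used to cross-check the
# package's evaluation primitives. Written deliberately from first
# principles (pixel counting, exhaustive loops) rather than sharing any code
# with the implementation under test.

# IoU by exact unit-pixel counting; boxes must have integer coordinates.
oracle_iou_pixelcount <- function(a, b) {
  xs <- min(a[1], b[1]):(max(a[3], b[3]) - 1)
  ys <- min(a[2], b[2]):(max(a[4], b[4]) - 1)
  inA <- outer(ys >= a[2] & ys < a[4], xs >= a[1] & xs < a[3], "&")
  inB <- outer(ys >= b[2] & ys < b[4], xs >= b[1] & xs < b[3], "&")
  sum(inA & inB) / sum(inA | inB)
}

# plain closed-form IoU, written independently
oracle_iou <- function(a, b) {
  iw <- min(a[3], b[3]) - max(a[1], b[1])
  ih <- min(a[4], b[4]) - max(a[2], b[2])
  if (iw <= 0 || ih <= 0) return(0)
  inter <- iw * ih
  inter / ((a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter)
}

# O(n^2) greedy NMS reference: repeatedly take the best-scored remaining
# detection (ties: smaller x_min, then y_min) and drop same-class overlaps.
oracle_nms <- function(df, thr) {
  remaining <- seq_len(nrow(df))
  kept <- integer(0)
  while (length(remaining) > 0) {
    sc <- df$score[remaining]
    best <- remaining[order(-sc, df$x_min[remaining], df$y_min[remaining])][1]
    kept <- c(kept, best)
    drop <- c(best)
    for (j in remaining) {
      if (j == best || df$class_id[j] != df$class_id[best]) next
      o <- oracle_iou(as.numeric(df[best, c("x_min", "y_min", "x_max", "y_max")]),
                      as.numeric(df[j, c("x_min", "y_min", "x_max", "y_max")]))
      if (o > thr) drop <- c(drop, j)
    }
    remaining <- setdiff(remaining, drop)
  }
  sort(kept)
}

# exhaustive greedy matcher: detections in score order (stable ties), each
# claims the unmatched same-class gt with max IoU >= thr
oracle_match <- function(dets, gts, thr) {
  ord <- order(-dets$score, dets$x_min, dets$y_min)
  used <- rep(FALSE, nrow(gts))
  tp <- 0
  tp_flags <- logical(nrow(dets))
  for (i in ord) {
    best_j <- 0; best_o <- -1
    for (j in seq_len(nrow(gts))) {
      if (used[j] || gts$class_id[j] != dets$class_id[i]) next
      o <- oracle_iou(as.numeric(dets[i, c("x_min", "y_min", "x_max", "y_max")]),
                      as.numeric(gts[j, c("x_min", "y_min", "x_max", "y_max")]))
      if (o >= thr && o > best_o) { best_o <- o; best_j <- j }
    }
    if (best_j > 0) { used[best_j] <- TRUE; tp <- tp + 1; tp_flags[i] <- TRUE }
  }
  list(TP = tp, FP = nrow(dets) - tp, FN = sum(!used), tp_flags = tp_flags,
       order = ord)
}

# rank-enumeration AP for one class: walk the ranking, record (R, P) after
# every detection, integrate max-precision-to-the-right over recall steps
oracle_ap_class <- function(dets, gts, thr) {
  if (nrow(dets) == 0) return(0)
  m <- oracle_match(dets, gts, thr)
  flags <- m$tp_flags[m$order]
  n_gt <- nrow(gts)
  P <- R <- numeric(length(flags))
  for (k in seq_along(flags)) {
    tpk <- sum(flags[1:k])
    P[k] <- tpk / k
    R[k] <- if (n_gt > 0) tpk / n_gt else 0
  }
  ap <- 0
  prevR <- 0
  for (k in seq_along(flags)) {
    if (R[k] > prevR) {
      ap <- ap + (R[k] - prevR) * max(P[k:length(P)])
      prevR <- R[k]
    }
  }
  ap
}

# random detection/ground-truth instances on an integer grid
random_instance <- function(n_det, n_gt, K = 2, size = 50) {
  rbox <- function(n) {
    x1 <- sample(0:(size - 6), n, replace = TRUE)
    y1 <- sample(0:(size - 6), n, replace = TRUE)
    data.frame(x_min = x1, y_min = y1,
               x_max = x1 + sample(2:12, n, replace = TRUE),
               y_max = y1 + sample(2:12, n, replace = TRUE))
  }
  dets <- rbox(n_det)
  dets$class_id <- sample(K, n_det, replace = TRUE)
  dets$score <- round(runif(n_det), 3)
  gts <- rbox(n_gt)
  gts$class_id <- sample(K, n_gt, replace = TRUE)
  list(dets = dets, gts = gts)
}
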