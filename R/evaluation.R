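## Detection evaluation protocol: IoU, greedy matching, precision/recall/F1,
## average precision, NMS, and the false-positive decomposition curves.

.as_box_df <- function(b) {
  if (is.data.frame(b)) return(b)
  if (is.numeric(b) && length(b) == 4L)
    return(data.frame(x_min = b[1], y_min = b[2], x_max = b[3], y_max = b[4]))
  stop("expected a box as c(x_min, y_min, x_max, y_max) or a data.frame")
}

#' Intersection over union of two boxes
#'
#' @param a,b boxes as `c(x_min, y_min, x_max, y_max)` or single-row
#'   data.frames.
#' @return IoU in `[0, 1]`.
#' @export
iou <- function(a, b) {
  a <- .as_box_df(a); b <- .as_box_df(b)
  if ((a$x_max - a$x_min) * (a$y_max - a$y_min) <= 0 ||
      (b$x_max - b$x_min) * (b$y_max - b$y_min) <= 0)
    stop("degenerate (zero-area) box")
  iouMatrix(a, b)[1, 1]
}

#' Pairwise IoU matrix
#'
#' @param A,B data.frames of boxes with x_min, y_min, x_max, y_max columns.
#' @return `nrow(A) x nrow(B)` matrix of IoU values.
#' @export
iouMatrix <- function(A, B) {
  n <- nrow(A); m <- nrow(B)
  ix1 <- pmax(matrix(A$x_min, n, m), matrix(B$x_min, n, m, byrow = TRUE))
  iy1 <- pmax(matrix(A$y_min, n, m), matrix(B$y_min, n, m, byrow = TRUE))
  ix2 <- pmin(matrix(A$x_max, n, m), matrix(B$x_max, n, m, byrow = TRUE))
  iy2 <- pmin(matrix(A$y_max, n, m), matrix(B$y_max, n, m, byrow = TRUE))
  inter <- pmax(ix2 - ix1, 0) * pmax(iy2 - iy1, 0)
  areaA <- (A$x_max - A$x_min) * (A$y_max - A$y_min)
  areaB <- (B$x_max - B$x_min) * (B$y_max - B$y_min)
  un <- matrix(areaA, n, m) + matrix(areaB, n, m, byrow = TRUE) - inter
  inter / un
}

# stable detection ordering: score desc, then x_min asc, then y_min asc
.det_order <- function(d) order(-d$score, d$x_min, d$y_min)

#' Greedy non-maximum suppression
#'
#' Keeps the highest-scored detection, suppresses same-class detections
#' with IoU strictly above `thresh`, and repeats. Ties are broken stably by
#' (score desc, x_min asc, y_min asc).
#'
#' @param dets data.frame with box columns, `class_id` and `score`.
#' @param thresh IoU suppression threshold in (0, 1].
#' @return The surviving subset of `dets`, in suppression order.
#' @export
nms <- function(dets, thresh = 0.5) {
  if (thresh <= 0 || thresh > 1) stop("thresh must lie in (0, 1]")
  if (nrow(dets) == 0L) return(dets)
  keep <- integer(0)
  for (cls in unique(dets$class_id)) {
    idx <- which(dets$class_id == cls)
    d <- dets[idx, , drop = FALSE]
    ord <- idx[.det_order(d)]
    while (length(ord) > 0L) {
      i <- ord[1]
      keep <- c(keep, i)
      ord <- ord[-1]
      if (length(ord) > 0L) {
        ious <- iouMatrix(dets[i, , drop = FALSE], dets[ord, , drop = FALSE])[1, ]
        ord <- ord[ious <= thresh]
      }
    }
  }
  out <- dets[keep, , drop = FALSE]
  out <- out[.det_order(out), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# greedy matching flags for one image's detections against its gts;
# returns logical TP flags (in the given detection order) and matched gt ids
.match_one <- function(dets, gts, iou_thresh) {
  nd <- nrow(dets); ng <- nrow(gts)
  tp <- logical(nd); matched_gt <- rep(NA_integer_, nd)
  gt_used <- logical(ng)
  if (nd > 0L && ng > 0L) {
    M <- iouMatrix(dets, gts)
    for (i in seq_len(nd)) {
      cand <- which(!gt_used & gts$class_id == dets$class_id[i] &
                      M[i, ] >= iou_thresh)
      if (length(cand) > 0L) {
        j <- cand[which.max(M[i, cand])]
        tp[i] <- TRUE; matched_gt[i] <- j; gt_used[j] <- TRUE
      }
    }
  }
  list(tp = tp, matched_gt = matched_gt, gt_matched = gt_used)
}

#' Match detections to ground truth
#'
#' Greedy, score-descending matching: each detection takes the unmatched
#' same-class ground-truth box with highest IoU at or above `iou_thresh`,
#' otherwise counts as a false positive; unmatched ground truths are false
#' negatives. When both inputs carry an `image_id` column, matching is per
#' image.
#'
#' @param dets detections data.frame (box columns, `class_id`, `score`).
#' @param gts ground-truth data.frame (box columns, `class_id`).
#' @param iou_thresh IoU acceptance threshold.
#' @return list of class `"MatchResult"`: `detections` (input rows plus
#'   `tp` flag and `matched_gt`), `gt_matched` logical, and counts `TP`,
#'   `FP`, `FN`.
#' @export
matchDetections <- function(dets, gts, iou_thresh = 0.5) {
  by_image <- "image_id" %in% names(dets) && "image_id" %in% names(gts)
  ord <- .det_order(dets)
  dets <- dets[ord, , drop = FALSE]
  tp <- logical(nrow(dets)); matched <- rep(NA_integer_, nrow(dets))
  gt_matched <- logical(nrow(gts))
  img_ids <- if (by_image) unique(c(dets$image_id, gts$image_id)) else "all"
  for (im in img_ids) {
    di <- if (by_image) which(dets$image_id == im) else seq_len(nrow(dets))
    gi <- if (by_image) which(gts$image_id == im) else seq_len(nrow(gts))
    m <- .match_one(dets[di, , drop = FALSE], gts[gi, , drop = FALSE], iou_thresh)
    tp[di] <- m$tp
    matched[di] <- gi[m$matched_gt]
    gt_matched[gi] <- m$gt_matched
  }
  res <- list(detections = cbind(dets, data.frame(tp = tp, matched_gt = matched)),
              gt_matched = gt_matched,
              TP = sum(tp), FP = sum(!tp), FN = sum(!gt_matched))
  class(res) <- "MatchResult"
  res
}

#' @export
print.MatchResult <- function(x, ...) {
  cat(sprintf("MatchResult: TP=%d FP=%d FN=%d\n", x$TP, x$FP, x$FN))
  invisible(x)
}

#' Precision, recall and F1 from match counts
#'
#' P = TP/(TP+FP), R = TP/(TP+FN), F1 = 2PR/(P+R), with the conventions
#' P = 0 when TP+FP = 0, R = 0 when TP+FN = 0, F1 = 0 when P+R = 0.
#'
#' @param m a `"MatchResult"`, or TP count.
#' @param FP,FN counts when `m` is given as the TP count.
#' @return Named numeric vector (P, R, F1).
#' @export
precisionRecallF1 <- function(m, FP = NULL, FN = NULL) {
  if (is(m, "MatchResult")) { TP <- m$TP; FP <- m$FP; FN <- m$FN } else TP <- m
  P <- if (TP + FP > 0) TP / (TP + FP) else 0
  R <- if (TP + FN > 0) TP / (TP + FN) else 0
  F1 <- if (P + R > 0) 2 * P * R / (P + R) else 0
  c(P = P, R = R, F1 = F1)
}

# ranked PR points for a set of detections with tp flags and a gt total
.pr_points <- function(score, tp, n_gt) {
  ord <- order(-score)
  tp <- tp[ord]
  ctp <- cumsum(tp); cfp <- cumsum(!tp)
  list(recall = if (n_gt > 0) ctp / n_gt else ctp * 0,
       precision = ctp / pmax(ctp + cfp, 1))
}

# area under the precision envelope (all-point interpolated AP)
.ap_area <- function(recall, precision, interpolation = "all_point") {
  if (length(recall) == 0L) return(0)
  if (interpolation == "eleven_point") {
    pts <- seq(0, 1, by = 0.1)
    return(mean(vapply(pts, function(t) {
      sel <- recall >= t - 1e-12
      if (any(sel)) max(precision[sel]) else 0
    }, 0)))
  }
  r <- c(0, recall); p <- c(0, precision)
  # precision envelope: running max from the right
  p_env <- rev(cummax(rev(p)))
  sum(diff(r) * p_env[-1])
}

#' Average precision per class
#'
#' Detections are ranked by descending score and matched greedily (per
#' image when `image_id` is present); AP is the area under the precision
#' envelope over recall ("all-point" interpolation, the modern convention)
#' or the 11-point interpolated mean. Classes absent from the ground truth
#' are excluded from the mean.
#'
#' @inheritParams matchDetections
#' @param interpolation `"all_point"` (default) or `"eleven_point"`.
#' @return list with `per_class` (named numeric) and `mean`.
#' @export
averagePrecision <- function(dets, gts, iou_thresh = 0.5,
                             interpolation = c("all_point", "eleven_point")) {
  interpolation <- match.arg(interpolation)
  classes <- sort(unique(gts$class_id))
  ap <- setNames(numeric(length(classes)), as.character(classes))
  for (ci in seq_along(classes)) {
    cls <- classes[ci]
    d <- dets[dets$class_id == cls, , drop = FALSE]
    g <- gts[gts$class_id == cls, , drop = FALSE]
    if (nrow(d) == 0L) { ap[ci] <- 0; next }
    m <- matchDetections(d, g, iou_thresh)
    pr <- .pr_points(m$detections$score, m$detections$tp, nrow(g))
    ap[ci] <- .ap_area(pr$recall, pr$precision, interpolation)
  }
  list(per_class = ap, mean = if (length(ap) > 0) mean(ap) else 0)
}

#' False-positive decomposition curves
#'
#' Seven pooled precision-recall curves characterising the error profile.
#' C50, C40 and LOC are the PR curves at IoU 0.5, 0.4 and 0.1 — moving from
#' C50 to LOC removes localisation errors. SIM additionally removes
#' errors from *similar* categories: false positives that overlap
#' (IoU >= 0.1) an unmatched ground-truth box of another class in the same
#' supercategory are credited as correct (consuming that ground truth).
#' CLS does the same for any-class overlaps, removing all classification
#' errors. BGR then drops the remaining (background) false positives, and
#' FIN also removes the false negatives, giving the perfect curve with
#' area 1.
#'
#' @inheritParams matchDetections
#' @param similarity_map named list mapping class ids (as character) to
#'   supercategory labels; by default all classes share one supercategory.
#' @return list of class `"PRCurveSet"`: per curve, `recall`, `precision`
#'   and `area`, in the order C50, C40, LOC, SIM, CLS, BGR, FIN.
#' @export
fpAnalysis <- function(dets, gts, similarity_map = NULL) {
  classes <- sort(unique(c(dets$class_id, gts$class_id)))
  if (is.null(similarity_map))
    similarity_map <- setNames(as.list(rep("object", length(classes))),
                               as.character(classes))
  n_gt <- nrow(gts)
  curve_from <- function(d, tp) {
    pr <- .pr_points(d$score, tp, n_gt)
    list(recall = pr$recall, precision = pr$precision,
         area = .ap_area(pr$recall, pr$precision))
  }
  flags_at <- function(thr) matchDetections(dets, gts, thr)
  out <- list()
  d50 <- flags_at(0.5)$detections
  out$C50 <- curve_from(d50, d50$tp)
  d40 <- flags_at(0.4)$detections
  out$C40 <- curve_from(d40, d40$tp)
  mloc <- flags_at(0.1)
  dloc <- mloc$detections
  out$LOC <- curve_from(dloc, dloc$tp)
  # credit FPs that overlap an unmatched gt of an admissible class as TPs,
  # greedily in score order, consuming the ground truth
  recover <- function(tp, gt_used, admissible) {
    if (n_gt == 0L) return(list(tp = tp, gt_used = gt_used))
    M <- iouMatrix(dloc, gts)
    same_img <- if ("image_id" %in% names(dloc) && "image_id" %in% names(gts))
      outer(dloc$image_id, gts$image_id, "==") else
      matrix(TRUE, nrow(dloc), n_gt)
    for (i in which(!tp)) {
      cand <- which(!gt_used & admissible[i, ] & same_img[i, ] & M[i, ] >= 0.1)
      if (length(cand) > 0L) {
        j <- cand[which.max(M[i, cand])]
        tp[i] <- TRUE; gt_used[j] <- TRUE
      }
    }
    list(tp = tp, gt_used = gt_used)
  }
  sc_det <- unlist(similarity_map[as.character(dloc$class_id)])
  sc_gt <- unlist(similarity_map[as.character(gts$class_id)])
  similar <- outer(sc_det, sc_gt, "==") &
    outer(dloc$class_id, gts$class_id, "!=")
  st_sim <- recover(dloc$tp, mloc$gt_matched, similar)
  out$SIM <- curve_from(dloc, st_sim$tp)
  st_cls <- recover(st_sim$tp, st_sim$gt_used,
                    matrix(TRUE, nrow(dloc), max(n_gt, 1L)))
  out$CLS <- curve_from(dloc, st_cls$tp)
  out$BGR <- curve_from(dloc[st_cls$tp, , drop = FALSE],
                        rep(TRUE, sum(st_cls$tp)))
  out$FIN <- list(recall = c(0, 1), precision = c(1, 1), area = 1)
  class(out) <- "PRCurveSet"
  out
}

#' @export
print.PRCurveSet <- function(x, ...) {
  cat("PR curve areas:\n")
  print(vapply(unclass(x), function(c) round(c$area, 4), 0))
  invisible(x)
}

#' Evaluate a detection run against ground truth
#'
#' Pools matches over all images (micro-averaging) before computing
#' precision, recall, F1 and AP per class, per view group, and their mean
#' over classes. Two named protocols are provided: `"standard"` (IoU 0.5,
#' score threshold from `score_threshold`) and `"deepfruits"` (IoU 0.4,
#' only detections with score > 0.9 considered).
#'
#' @param dets detections data.frame with `image_id`, box columns,
#'   `class_id`, `score`.
#' @param gts ground-truth data.frame with `image_id`, box columns,
#'   `class_id`, and optionally `view`.
#' @param protocol `"standard"` or `"deepfruits"`.
#' @param score_threshold score cut-off for the standard protocol.
#' @param interpolation AP interpolation, see [averagePrecision()].
#' @param class_names optional named character vector mapping class id to
#'   name for the report.
#' @return list of class `"EvalReport"` with a `table` data.frame
#'   (view_group, class, TP, FP, FN, P, R, F1, AP).
#' @export
evaluateRun <- function(dets, gts, protocol = c("standard", "deepfruits"),
                        score_threshold = 0.5,
                        interpolation = c("all_point", "eleven_point"),
                        class_names = NULL) {
  protocol <- match.arg(protocol)
  interpolation <- match.arg(interpolation)
  if (nrow(dets) > 0L && !all(dets$image_id %in% gts$image_id) &&
      nrow(gts) > 0L)
    stop("detections reference image ids absent from the ground truth")
  iou_thr <- if (protocol == "deepfruits") 0.4 else 0.5
  if (protocol == "deepfruits") {
    dets <- dets[dets$score > 0.9, , drop = FALSE]
  } else {
    dets <- dets[dets$score >= score_threshold, , drop = FALSE]
  }
  views <- if ("view" %in% names(gts)) unique(gts$view) else character(0)
  groups <- list(overall = unique(gts$image_id))
  if ("V1" %in% views)
    groups$V1 <- unique(gts$image_id[gts$view == "V1"])
  if (any(c("V2", "V3") %in% views))
    groups[["V2-3"]] <- unique(gts$image_id[gts$view %in% c("V2", "V3")])
  classes <- sort(unique(gts$class_id))
  rows <- list()
  for (gname in names(groups)) {
    ids <- groups[[gname]]
    d <- dets[dets$image_id %in% ids, , drop = FALSE]
    g <- gts[gts$image_id %in% ids, , drop = FALSE]
    ap <- averagePrecision(d, g, iou_thr, interpolation)
    per <- list()
    for (cls in classes) {
      dc <- d[d$class_id == cls, , drop = FALSE]
      gc <- g[g$class_id == cls, , drop = FALSE]
      m <- matchDetections(dc, gc, iou_thr)
      prf <- precisionRecallF1(m)
      nm <- if (!is.null(class_names)) class_names[[as.character(cls)]] else
        as.character(cls)
      per[[length(per) + 1L]] <- data.frame(
        view_group = gname, class = nm, TP = m$TP, FP = m$FP, FN = m$FN,
        P = prf["P"], R = prf["R"], F1 = prf["F1"],
        AP = unname(ap$per_class[as.character(cls)]))
    }
    tab <- do.call(rbind, per)
    agg <- matchDetections(d, g, iou_thr)
    prf <- precisionRecallF1(agg)
    tab <- rbind(tab, data.frame(
      view_group = gname, class = "mean", TP = agg$TP, FP = agg$FP,
      FN = agg$FN, P = prf["P"], R = prf["R"], F1 = prf["F1"],
      AP = ap$mean))
    rows[[length(rows) + 1L]] <- tab
  }
  out <- list(protocol = protocol, iou_threshold = iou_thr,
              score_threshold = if (protocol == "deepfruits") 0.9 else
                score_threshold,
              table = do.call(rbind, rows))
  rownames(out$table) <- NULL
  class(out) <- "EvalReport"
  out
}

#' @export
print.EvalReport <- function(x, ...) {
  cat(sprintf("EvalReport (%s protocol: IoU %.2f, score %s %.2f)\n",
              x$protocol, x$iou_threshold,
              if (x$protocol == "deepfruits") ">" else ">=",
              x$score_threshold))
  tab <- x$table
  tab[c("P", "R", "F1", "AP")] <- round(tab[c("P", "R", "F1", "AP")], 4)
  print(tab)
  invisible(x)
}
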