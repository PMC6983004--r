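## One-stage anchor-based detector: ResNet-18-style backbone, 5-level
## feature pyramid (F3..F7), shared classification/regression sub-nets,
## anchor machinery, box coding, and inference-time decoding.

#' Detector configuration
#'
#' @param input_channels network input depth D; 3 (RGB or Lab alone) or 6
#'   (early fusion).
#' @param num_classes number of object classes K.
#' @param anchor_scales per-location anchor scale multipliers; default
#'   `2^(0:2/3)`.
#' @param anchor_ratios height/width aspect ratios; default `c(0.5, 1, 2)`.
#' @param anchor_base_factor anchor base size at pyramid level l is
#'   `anchor_base_factor * 2^l` pixels.
#' @param backbone_width stem/stage-1 channel width (64 for the full model;
#'   smaller for desk-scale runs).
#' @param blocks_per_stage residual blocks per backbone stage.
#' @param fpn_channels pyramid channel width (256 for the full model).
#' @param head_depth number of 3x3 conv+ReLU layers in each sub-net tower.
#' @param focal_alpha,focal_gamma focal-loss parameters (defaults 0.25, 2).
#' @param score_threshold inference-time score cut-off.
#' @param nms_threshold IoU threshold for non-maximum suppression.
#' @param pos_iou,neg_iou anchor assignment thresholds; anchors with maximum
#'   IoU in `[neg_iou, pos_iou)` are ignored during training.
#' @param regression_head_activation `"linear"` (default) or `"sigmoid"`
#'   applied to the raw regression outputs.
#' @param prior_prob initial foreground probability encoded in the
#'   classification head's final bias.
#' @return A validated list of class `"ModelConfig"`.
#' @export
modelConfig <- function(input_channels = 6L, num_classes = 2L,
                        anchor_scales = 2^((0:2) / 3),
                        anchor_ratios = c(0.5, 1, 2),
                        anchor_base_factor = 4,
                        backbone_width = 64L, blocks_per_stage = 2L,
                        fpn_channels = 256L, head_depth = 4L,
                        focal_alpha = 0.25, focal_gamma = 2.0,
                        score_threshold = 0.5, nms_threshold = 0.5,
                        pos_iou = 0.5, neg_iou = 0.4,
                        regression_head_activation = c("linear", "sigmoid"),
                        prior_prob = 0.01) {
  if (!input_channels %in% c(3L, 6L))
    stop("input_channels must be 3 or 6")
  if (num_classes < 1L) stop("num_classes must be >= 1")
  if (pos_iou <= neg_iou) stop("pos_iou must exceed neg_iou")
  cfg <- list(
    input_channels = as.integer(input_channels),
    num_classes = as.integer(num_classes),
    anchor_scales = anchor_scales, anchor_ratios = anchor_ratios,
    anchor_base_factor = anchor_base_factor,
    anchors_per_location = length(anchor_scales) * length(anchor_ratios),
    backbone_width = as.integer(backbone_width),
    blocks_per_stage = as.integer(blocks_per_stage),
    fpn_channels = as.integer(fpn_channels),
    head_depth = as.integer(head_depth),
    focal_alpha = focal_alpha, focal_gamma = focal_gamma,
    score_threshold = score_threshold, nms_threshold = nms_threshold,
    pos_iou = pos_iou, neg_iou = neg_iou,
    regression_head_activation = match.arg(regression_head_activation),
    prior_prob = prior_prob,
    channel_layout = if (input_channels == 6L)
      c("R", "G", "B", "L", "a", "b") else c("R", "G", "B"))
  class(cfg) <- "ModelConfig"
  cfg
}

#' @export
print.ModelConfig <- function(x, ...) {
  cat(sprintf(paste0(
    "ModelConfig: D=%d, K=%d, A=%d (scales %s x ratios %s)\n",
    "  backbone width %d (%d blocks/stage), FPN %d ch, head depth %d\n",
    "  focal alpha=%.2f gamma=%.2f; score>=%.2f, NMS %.2f, assign %g/%g\n"),
    x$input_channels, x$num_classes, x$anchors_per_location,
    paste(round(x$anchor_scales, 3), collapse = "/"),
    paste(x$anchor_ratios, collapse = "/"),
    x$backbone_width, x$blocks_per_stage, x$fpn_channels, x$head_depth,
    x$focal_alpha, x$focal_gamma, x$score_threshold, x$nms_threshold,
    x$pos_iou, x$neg_iou))
  invisible(x)
}

## parameter construction ----------------------------------------------------

#' Build a detector with freshly initialised weights
#'
#' Constructs the full parameter set: a 7x7 stride-2 stem to
#' `backbone_width` channels followed by a stride-2 max-pool, four
#' residual stages (strides 4/8/16/32), lateral + top-down pyramid layers
#' producing F3..F7, and the two shared sub-net towers. The final
#' classification bias is set to `-log((1-prior_prob)/prior_prob)` so the
#' untrained network predicts foreground with probability `prior_prob`.
#'
#' @param cfg a [modelConfig()].
#' @param seed integer seed for weight initialisation.
#' @return A list of class `"Detector"` with elements `params`, `cfg`, and
#'   (after training) `stats`, `class_names`.
#' @export
buildDetector <- function(cfg, seed = 1L) {
  stopifnot(is(cfg, "ModelConfig"))
  .with_seed(seed, {
    w <- cfg$backbone_width
    widths <- w * c(1L, 2L, 4L, 8L)
    P <- list()
    P$stem <- makeConvParam(cfg$input_channels, w, 7L)
    in_ch <- w
    for (s in 1:4) {
      out_ch <- widths[s]
      for (b in seq_len(cfg$blocks_per_stage)) {
        pre <- sprintf("s%db%d", s, b)
        c1_in <- if (b == 1L) in_ch else out_ch
        P[[paste0(pre, "c1")]] <- makeConvParam(c1_in, out_ch, 3L)
        P[[paste0(pre, "c2")]] <- makeConvParam(out_ch, out_ch, 3L)
        if (b == 1L && (s > 1L || in_ch != out_ch))
          P[[paste0(pre, "proj")]] <- makeConvParam(c1_in, out_ch, 1L)
      }
      in_ch <- out_ch
    }
    fc <- cfg$fpn_channels
    for (l in 3:5) P[[paste0("lat", l)]] <- makeConvParam(widths[l - 1L], fc, 1L)
    for (l in 3:5) P[[paste0("smooth", l)]] <- makeConvParam(fc, fc, 3L)
    P$f6 <- makeConvParam(fc, fc, 3L)
    P$f7 <- makeConvParam(fc, fc, 3L)
    A <- cfg$anchors_per_location
    for (i in seq_len(cfg$head_depth)) {
      P[[paste0("cls", i)]] <- makeConvParam(fc, fc, 3L)
      P[[paste0("reg", i)]] <- makeConvParam(fc, fc, 3L)
    }
    P$clsout <- makeConvParam(fc, cfg$num_classes * A, 3L,
                              bias_init = -log((1 - cfg$prior_prob) / cfg$prior_prob))
    P$clsout$W <- P$clsout$W * 0.01  # near-zero head so the prior bias rules
    P$regout <- makeConvParam(fc, 4L * A, 3L)
    P$regout$W <- P$regout$W * 0.01
    P$regout$b[] <- 0
    structure(list(params = P, cfg = cfg, stats = NULL, class_names = NULL),
              class = "Detector")
  })
}

#' @export
print.Detector <- function(x, ...) {
  np <- sum(vapply(x$params, function(p) length(p$W) + length(p$b), 0))
  cat(sprintf("Detector: %d parameter tensors, %s weights%s\n",
              length(x$params), format(np, big.mark = ","),
              if (is.null(x$stats)) " (untrained)" else ""))
  print(x$cfg)
  invisible(x)
}

# evaluate seed-dependent code without disturbing the global RNG stream
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(as.integer(seed))
  expr
}

## forward pass ---------------------------------------------------------------

# Run backbone + pyramid + heads on one H x W x D array.
# Returns list(levels = list of list(cls=cube, reg=cube, cls_id, reg_id),
#              tape).  Input spatial dims must be divisible by 32.
detectorForward <- function(model, x) {
  d <- dim(x)
  if (d[1] %% 32L != 0L || d[2] %% 32L != 0L)
    stop(sprintf("input %dx%d not divisible by 32; run prepareImage() first",
                 d[1], d[2]))
  if (d[3] != model$cfg$input_channels)
    stop(sprintf("input depth %d does not match model D=%d", d[3],
                 model$cfg$input_channels))
  cfg <- model$cfg
  tp <- newTape(model$params)
  id <- tpInput(tp, x)
  id <- tpReLU(tp, tpConv(tp, id, "stem", stride = 2L, pad = 3L))
  id <- tpMaxPool(tp, id, k = 3L, stride = 2L, pad = 1L)
  stage_out <- integer(4)
  for (s in 1:4) {
    for (b in seq_len(cfg$blocks_per_stage)) {
      pre <- sprintf("s%db%d", s, b)
      stride <- if (b == 1L && s > 1L) 2L else 1L
      h <- tpReLU(tp, tpConv(tp, id, paste0(pre, "c1"), stride = stride, pad = 1L))
      h <- tpConv(tp, h, paste0(pre, "c2"), stride = 1L, pad = 1L)
      short <- if (!is.null(tp$params[[paste0(pre, "proj")]]))
        tpConv(tp, id, paste0(pre, "proj"), stride = stride, pad = 0L) else id
      id <- tpReLU(tp, tpAdd(tp, h, short))
    }
    stage_out[s] <- id
  }
  # FPN: lateral 1x1, top-down upsample-add, 3x3 smoothing; F6/F7 from F5
  lat5 <- tpConv(tp, stage_out[4], "lat5", stride = 1L, pad = 0L)
  lat4 <- tpConv(tp, stage_out[3], "lat4", stride = 1L, pad = 0L)
  lat3 <- tpConv(tp, stage_out[2], "lat3", stride = 1L, pad = 0L)
  td4 <- tpAdd(tp, lat4, tpUpsample2(tp, lat5))
  td3 <- tpAdd(tp, lat3, tpUpsample2(tp, td4))
  f5 <- tpConv(tp, lat5, "smooth5", stride = 1L, pad = 1L)
  f4 <- tpConv(tp, td4, "smooth4", stride = 1L, pad = 1L)
  f3 <- tpConv(tp, td3, "smooth3", stride = 1L, pad = 1L)
  f6 <- tpConv(tp, f5, "f6", stride = 2L, pad = 1L)
  f7 <- tpConv(tp, tpReLU(tp, f6), "f7", stride = 2L, pad = 1L)
  feats <- c(f3, f4, f5, f6, f7)
  levels <- vector("list", 5L)
  for (i in seq_along(feats)) {
    cid <- feats[i]
    rid <- feats[i]
    for (k in seq_len(cfg$head_depth)) {
      cid <- tpReLU(tp, tpConv(tp, cid, paste0("cls", k), stride = 1L, pad = 1L))
      rid <- tpReLU(tp, tpConv(tp, rid, paste0("reg", k), stride = 1L, pad = 1L))
    }
    cid <- tpConv(tp, cid, "clsout", stride = 1L, pad = 1L)
    rid <- tpConv(tp, rid, "regout", stride = 1L, pad = 1L)
    levels[[i]] <- list(cls = tp$vals[[cid]], reg = tp$vals[[rid]],
                        cls_id = cid, reg_id = rid, level = i + 2L)
  }
  list(levels = levels, tape = tp)
}

#' Pyramid feature-map shapes for a given input size
#'
#' Spatial sizes of F3..F7 under the network's stride arithmetic (each
#' stride-2 layer maps n to ceiling(n/2), so level l sits at
#' ceiling(input/2^l)).
#'
#' @param height,width input spatial size in pixels.
#' @return A list of five `c(h, w)` pairs named `F3`..`F7`.
#' @export
pyramidShapes <- function(height, width) {
  out <- list()
  for (l in 3:7)
    out[[paste0("F", l)]] <- c(ceiling(height / 2^l), ceiling(width / 2^l))
  out
}

## anchors and box coding -----------------------------------------------------

#' Generate the dense anchor grid
#'
#' For each pyramid level l and each feature-map cell, places
#' `length(scales) * length(ratios)` anchor boxes centred on the cell
#' centre in input-pixel coordinates, with base size
#' `anchor_base_factor * 2^l`. Anchors are ordered level-major, then
#' anchor-index (scale fastest within ratio), then column, then row —
#' matching the memory layout of the head output maps.
#'
#' @param shapes list of `c(h, w)` per level as from [pyramidShapes()].
#' @param cfg a [modelConfig()].
#' @param levels integer pyramid levels corresponding to `shapes`
#'   (default 3:7).
#' @return data.frame with columns x_min, y_min, x_max, y_max, level.
#' @export
generateAnchors <- function(shapes, cfg, levels = 3:7) {
  if (length(shapes) == 0L) stop("empty pyramid")
  A <- cfg$anchors_per_location
  combos <- expand.grid(scale = cfg$anchor_scales, ratio = cfg$anchor_ratios)
  out <- vector("list", length(shapes))
  for (i in seq_along(shapes)) {
    l <- levels[i]
    hw <- shapes[[i]]
    stride <- 2^l
    base <- cfg$anchor_base_factor * stride
    cy <- (seq_len(hw[1]) - 0.5) * stride
    cx <- (seq_len(hw[2]) - 0.5) * stride
    # ordering: anchor index slowest, then column, then row (row fastest)
    grid <- expand.grid(cy = cy, cx = cx)
    per <- vector("list", A)
    for (a in seq_len(A)) {
      wa <- base * combos$scale[a] / sqrt(combos$ratio[a])
      ha <- base * combos$scale[a] * sqrt(combos$ratio[a])
      per[[a]] <- data.frame(x_min = grid$cx - wa / 2, y_min = grid$cy - ha / 2,
                             x_max = grid$cx + wa / 2, y_max = grid$cy + ha / 2,
                             level = l)
    }
    out[[i]] <- do.call(rbind, per)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

.box_cwh <- function(b) {
  w <- b$x_max - b$x_min
  h <- b$y_max - b$y_min
  list(cx = b$x_min + w / 2, cy = b$y_min + h / 2, w = w, h = h)
}

#' Box offset coding
#'
#' `encodeBoxes` expresses ground-truth boxes as offsets from paired
#' anchors: tx = (cx_gt - cx_a)/w_a, ty = (cy_gt - cy_a)/h_a,
#' tw = log(w_gt/w_a), th = log(h_gt/h_a). `decodeBoxes` is the exact
#' inverse, with optional clipping to image bounds.
#'
#' @param anchors,boxes data.frames with columns x_min, y_min, x_max, y_max,
#'   row-paired.
#' @return `encodeBoxes`: an n x 4 matrix (tx, ty, tw, th).
#' @export
encodeBoxes <- function(anchors, boxes) {
  a <- .box_cwh(anchors); g <- .box_cwh(boxes)
  if (any(a$w <= 0) || any(a$h <= 0) || any(g$w <= 0) || any(g$h <= 0))
    stop("boxes and anchors must have strictly positive width and height")
  cbind(tx = (g$cx - a$cx) / a$w, ty = (g$cy - a$cy) / a$h,
        tw = log(g$w / a$w), th = log(g$h / a$h))
}

#' @rdname encodeBoxes
#' @param offsets n x 4 matrix (tx, ty, tw, th).
#' @param clip_hw optional `c(height, width)` to clip decoded boxes to.
#' @return `decodeBoxes`: data.frame of decoded boxes.
#' @export
decodeBoxes <- function(anchors, offsets, clip_hw = NULL) {
  a <- .box_cwh(anchors)
  cx <- a$cx + offsets[, 1] * a$w
  cy <- a$cy + offsets[, 2] * a$h
  w <- a$w * exp(offsets[, 3])
  h <- a$h * exp(offsets[, 4])
  b <- data.frame(x_min = cx - w / 2, y_min = cy - h / 2,
                  x_max = cx + w / 2, y_max = cy + h / 2)
  if (!is.null(clip_hw)) {
    b$x_min <- pmin(pmax(b$x_min, 0), clip_hw[2])
    b$x_max <- pmin(pmax(b$x_max, 0), clip_hw[2])
    b$y_min <- pmin(pmax(b$y_min, 0), clip_hw[1])
    b$y_max <- pmin(pmax(b$y_max, 0), clip_hw[1])
  }
  b
}

#' Assign anchors to ground-truth boxes for training
#'
#' Each anchor takes the ground-truth box with which it has maximum IoU.
#' Anchors at IoU >= `pos_iou` become positives with that box's class;
#' anchors below `neg_iou` become background; the band in between is
#' ignored. Positive anchors receive regression targets from
#' [encodeBoxes()].
#'
#' @param anchors anchor data.frame from [generateAnchors()].
#' @param annotations data.frame with box columns and `class_id` (1..K);
#'   zero rows mean every anchor is background.
#' @param pos_iou,neg_iou assignment thresholds (defaults 0.5 / 0.4).
#' @return list with `labels` (-1 ignore, 0 background, k = class id),
#'   `matched_gt` (index into annotations, NA when background/ignore),
#'   `reg_targets` (n x 4 matrix, rows valid where labels > 0).
#' @export
assignTargets <- function(anchors, annotations, pos_iou = 0.5, neg_iou = 0.4) {
  if (pos_iou <= neg_iou) stop("pos_iou must exceed neg_iou")
  n <- nrow(anchors)
  labels <- integer(n)
  matched <- rep(NA_integer_, n)
  reg <- matrix(0, n, 4L)
  if (!is.null(annotations) && nrow(annotations) > 0L) {
    M <- iouMatrix(anchors, annotations)
    best <- max.col(M, ties.method = "first")
    best_iou <- M[cbind(seq_len(n), best)]
    pos <- best_iou >= pos_iou
    ign <- !pos & best_iou >= neg_iou
    labels[ign] <- -1L
    labels[pos] <- as.integer(annotations$class_id[best[pos]])
    matched[pos] <- best[pos]
    if (any(pos))
      reg[pos, ] <- encodeBoxes(anchors[pos, , drop = FALSE],
                                annotations[best[pos], , drop = FALSE])
  }
  list(labels = labels, matched_gt = matched, reg_targets = reg)
}

## gather / scatter between head maps and the anchor-major layout -------------

# cls cube (H,W,K*A) -> n_l x K matrix in anchor order; reg likewise n_l x 4
gatherLevel <- function(cls, reg, K, A) {
  hw <- dim(cls)[1] * dim(cls)[2]
  sc <- matrix(0, hw * A, K)
  for (k in seq_len(K)) sc[, k] <- as.vector(cls[, , (seq_len(A) - 1L) * K + k])
  rg <- matrix(0, hw * A, 4L)
  for (j in 1:4) rg[, j] <- as.vector(reg[, , (seq_len(A) - 1L) * 4L + j])
  list(cls = sc, reg = rg)
}

# inverse: anchor-order gradient matrices -> head-map gradient cubes
scatterLevel <- function(g_cls, g_reg, hl, wl, K, A) {
  cls <- array(0, c(hl, wl, K * A))
  for (k in seq_len(K))
    cls[, , (seq_len(A) - 1L) * K + k] <- array(g_cls[, k], c(hl, wl, A))
  reg <- array(0, c(hl, wl, 4L * A))
  for (j in 1:4)
    reg[, , (seq_len(A) - 1L) * 4L + j] <- array(g_reg[, j], c(hl, wl, A))
  list(cls = cls, reg = reg)
}

## inference ------------------------------------------------------------------

.sigmoid <- function(z) 1 / (1 + exp(-z))

#' Run the detector on a prepared input tensor
#'
#' Forward pass, sigmoid scoring over all pyramid levels, score
#' thresholding, box decoding, and per-class NMS. If `record` is given,
#' boxes are mapped back to original-image coordinates through the
#' [prepareImage()] transform.
#'
#' @param model a trained or freshly built `"Detector"`.
#' @param input `H x W x D` array (spatially divisible by 32). Pass the
#'   standardized network input; [detectScene()] handles the front end.
#' @param score_threshold optional override of `cfg$score_threshold`.
#' @param record optional transform record from [prepareImage()].
#' @return data.frame of detections: x_min, y_min, x_max, y_max, class_id,
#'   score.
#' @export
forwardDetect <- function(model, input, score_threshold = NULL, record = NULL) {
  cfg <- model$cfg
  thr <- if (is.null(score_threshold)) cfg$score_threshold else score_threshold
  fw <- detectorForward(model, input)
  K <- cfg$num_classes; A <- cfg$anchors_per_location
  shapes <- lapply(fw$levels, function(lv) dim(lv$cls)[1:2])
  anchors <- generateAnchors(shapes, cfg)
  sc_all <- vector("list", 5L); rg_all <- vector("list", 5L)
  for (i in 1:5) {
    g <- gatherLevel(fw$levels[[i]]$cls, fw$levels[[i]]$reg, K, A)
    sc_all[[i]] <- .sigmoid(g$cls)
    rg_all[[i]] <- if (cfg$regression_head_activation == "sigmoid")
      .sigmoid(g$reg) else g$reg
  }
  scores <- do.call(rbind, sc_all)
  offsets <- do.call(rbind, rg_all)
  keep <- which(scores >= thr, arr.ind = TRUE)
  if (nrow(keep) == 0L)
    return(data.frame(x_min = numeric(0), y_min = numeric(0),
                      x_max = numeric(0), y_max = numeric(0),
                      class_id = integer(0), score = numeric(0)))
  ai <- keep[, 1]
  boxes <- decodeBoxes(anchors[ai, , drop = FALSE],
                       offsets[ai, , drop = FALSE], clip_hw = dim(input)[1:2])
  dets <- cbind(boxes, data.frame(class_id = as.integer(keep[, 2]),
                                  score = scores[keep]))
  dets <- dets[dets$x_max > dets$x_min & dets$y_max > dets$y_min, , drop = FALSE]
  dets <- nms(dets, cfg$nms_threshold)
  if (!is.null(record)) dets <- invertTransformOnBoxes(dets, record)
  rownames(dets) <- NULL
  dets
}

#' Inflate a 3-channel stem to 6 input channels
#'
#' Builds a 6-channel stem weight matrix from a 3-channel one by tiling the
#' RGB filters over the (R,G,B) and (L,a,b) channel groups and halving, so
#' the stem's response to a duplicated input is unchanged. Off by default
#' everywhere: detectors are trained from random initialisation, but this
#' utility lets a 3-channel stem (e.g. from an RGB-only run) seed an
#' early-fusion model.
#'
#' @param model a `"Detector"` with `input_channels = 6`.
#' @param stem3 a stem parameter from a 3-channel detector
#'   (`model3$params$stem`).
#' @return The model with its stem weights replaced.
#' @export
inflateStemChannels <- function(model, stem3) {
  if (model$cfg$input_channels != 6L)
    stop("target model must have 6 input channels")
  k2 <- stem3$kh * stem3$kw
  if (ncol(stem3$W) != 3L * k2)
    stop("stem3 must come from a 3-channel stem")
  model$params$stem$W <- cbind(stem3$W, stem3$W) / 2
  model$params$stem$b <- stem3$b
  model
}

## checkpoints ----------------------------------------------------------------

#' Save / load a detector checkpoint
#'
#' The checkpoint is a single serialized file holding the weights, the full
#' [modelConfig()] (including channel layout, so the input depth D is never
#' ambiguous), the fusion mode, input standardization statistics, and class
#' names.
#'
#' @param model a `"Detector"`.
#' @param path file path.
#' @export
saveCheckpoint <- function(model, path) {
  saveRDS(unclass(model), path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @return `loadCheckpoint`: the restored `"Detector"`.
#' @export
loadCheckpoint <- function(path) {
  m <- readRDS(path)
  class(m$cfg) <- "ModelConfig"
  structure(m, class = "Detector")
}
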