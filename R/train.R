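## Training loop and end-user operations tying the modules together:
## front end -> detector -> loss -> optimiser, plus scene-level inference
## and evaluation.

#' Run configuration
#'
#' @param fusion network input arm: `"early_fusion"` (D = 6),
#'   `"rgb"` or `"lab"` (D = 3).
#' @param model a [modelConfig()]; its `input_channels` must match
#'   `fusion`.
#' @param loss a [lossConfig()].
#' @param lr Adam learning rate (cosine-decayed to 0 over the run).
#' @param iterations number of optimisation steps.
#' @param batch_size images per step.
#' @param colour_mode RGB linearisation mode, see [rgbToXyz()].
#' @param seed master seed: weight init, batch order.
#' @param log_every record the loss every this many iterations.
#' @return list of class `"RunConfig"`.
#' @export
runConfig <- function(fusion = c("early_fusion", "rgb", "lab"),
                      model = NULL, loss = lossConfig(), lr = 1e-3,
                      iterations = 500L, batch_size = 2L,
                      colour_mode = c("srgb_linearized", "naive"),
                      seed = 1L, log_every = 10L) {
  fusion <- match.arg(fusion)
  colour_mode <- match.arg(colour_mode)
  D <- if (fusion == "early_fusion") 6L else 3L
  if (is.null(model)) model <- modelConfig(input_channels = D)
  if (model$input_channels != D)
    stop(sprintf("fusion '%s' needs D=%d but model has input_channels=%d",
                 fusion, D, model$input_channels))
  structure(list(fusion = fusion, model = model, loss = loss, lr = lr,
                 iterations = as.integer(iterations),
                 batch_size = as.integer(batch_size),
                 colour_mode = colour_mode, seed = as.integer(seed),
                 log_every = as.integer(log_every)),
            class = "RunConfig")
}

#' Build the network input for one scene under a fusion arm
#'
#' @param pixels `H x W x 3` gamma sRGB array in `[0,1]`.
#' @param fusion `"early_fusion"`, `"rgb"` or `"lab"`.
#' @param colour_mode see [rgbToXyz()].
#' @return `H x W x D` array; Lab channels are rescaled to `[0,1]` via
#'   [labFusionScaling()].
#' @export
buildNetworkInput <- function(pixels, fusion = "early_fusion",
                              colour_mode = "srgb_linearized") {
  switch(fusion,
    rgb = pixels,
    lab = {
      lab <- pixels(rgbToLab(ColourImage(pixels), mode = colour_mode))
      sc <- labFusionScaling()
      for (c in 1:3) lab[, , c] <- (lab[, , c] - sc$mean[c]) / sc$sd[c]
      lab
    },
    early_fusion = {
      lab <- rgbToLab(ColourImage(pixels), mode = colour_mode)
      pixels(earlyFuse(pixels, lab))
    },
    stop("unknown fusion arm: ", fusion))
}

# per-scene loss gradient; returns seeds for tpBackward plus loss parts
.loss_and_seeds <- function(fw, target, cfg, loss_cfg) {
  K <- cfg$num_classes; A <- cfg$anchors_per_location
  gl <- lapply(fw$levels, function(lv) gatherLevel(lv$cls, lv$reg, K, A))
  z <- do.call(rbind, lapply(gl, `[[`, "cls"))
  raw_reg <- do.call(rbind, lapply(gl, `[[`, "reg"))
  labels <- target$labels
  npos <- max(1, sum(labels > 0L))
  y <- matrix(0, nrow(z), K)
  pos <- which(labels > 0L)
  if (length(pos) > 0L) y[cbind(pos, labels[pos])] <- 1
  excl <- matrix(labels < 0L, nrow(z), K)
  fg <- focalLossGrad(z, y, loss_cfg$alpha, loss_cfg$gamma, npos, exclude = excl)
  reg_pred <- raw_reg
  dsig <- NULL
  if (cfg$regression_head_activation == "sigmoid") {
    s <- .sigmoid(raw_reg)
    dsig <- s * (1 - s)
    reg_pred <- s
  }
  g_reg <- matrix(0, nrow(raw_reg), 4L)
  reg_loss <- 0
  if (length(pos) > 0L) {
    rg <- regressionLossGrad(reg_pred[pos, , drop = FALSE],
                             target$reg_targets[pos, , drop = FALSE])
    reg_loss <- rg$loss
    g_reg[pos, ] <- rg$grad
  }
  if (!is.null(dsig)) g_reg <- g_reg * dsig
  # split gradient rows back into levels and scatter onto the head maps
  seeds <- list()
  off <- 0L
  for (i in seq_along(fw$levels)) {
    lv <- fw$levels[[i]]
    hl <- dim(lv$cls)[1]; wl <- dim(lv$cls)[2]
    n_l <- hl * wl * A
    rows <- off + seq_len(n_l)
    sc <- scatterLevel(fg$grad[rows, , drop = FALSE],
                       g_reg[rows, , drop = FALSE], hl, wl, K, A)
    seeds[[as.character(lv$cls_id)]] <- sc$cls
    seeds[[as.character(lv$reg_id)]] <- sc$reg
    off <- off + n_l
  }
  list(seeds = seeds, cls_loss = fg$loss, reg_loss = reg_loss,
       total = totalLoss(fg$loss, reg_loss))
}

#' Train the detector on annotated scenes
#'
#' Builds the fusion-arm inputs, standardizes them with pooled channel
#' statistics, precomputes anchors and target assignments, and optimises
#' the focal + smooth-L1 objective with Adam under a cosine learning-rate
#' decay. Fully deterministic given the run seed.
#'
#' @param scenes list of scenes, each a list with `pixels`
#'   (`H x W x 3` gamma sRGB array) and `annotations` (data.frame with box
#'   columns and `class_id`). [generateScene()] output fits directly.
#' @param cfg a [runConfig()].
#' @param class_names character vector naming class ids.
#' @param verbose print a line every `log_every` iterations.
#' @return A trained `"Detector"` carrying `stats`, `fusion`,
#'   `class_names` and the training `log` (data.frame).
#' @export
trainDetector <- function(scenes, cfg, class_names = c("ripe", "unripe"),
                          verbose = FALSE) {
  stopifnot(is(cfg, "RunConfig"))
  mcfg <- cfg$model
  inputs <- lapply(scenes, function(sc)
    prepareImage(buildNetworkInput(sc$pixels, cfg$fusion, cfg$colour_mode))$image)
  stats <- estimateChannelStats(inputs)
  inputs <- lapply(inputs, standardizeTensor, stats = stats)
  sizes <- vapply(inputs, function(x) paste(dim(x)[1:2], collapse = "x"), "")
  anchor_cache <- list()
  targets <- vector("list", length(scenes))
  for (i in seq_along(scenes)) {
    key <- sizes[i]
    if (is.null(anchor_cache[[key]])) {
      d <- dim(inputs[[i]])
      anchor_cache[[key]] <- generateAnchors(pyramidShapes(d[1], d[2]), mcfg)
    }
    targets[[i]] <- assignTargets(anchor_cache[[key]], scenes[[i]]$annotations,
                                  mcfg$pos_iou, mcfg$neg_iou)
  }
  model <- buildDetector(mcfg, seed = cfg$seed)
  state <- newAdamState(model$params)
  log <- list()
  .with_seed(cfg$seed + 1L, {
    for (it in seq_len(cfg$iterations)) {
      lr_t <- cfg$lr * 0.5 * (1 + cos(pi * (it - 1) / cfg$iterations))
      batch <- sample(length(scenes), min(cfg$batch_size, length(scenes)))
      grads <- NULL
      cls_l <- reg_l <- 0
      for (b in batch) {
        fw <- detectorForward(model, inputs[[b]])
        ls <- .loss_and_seeds(fw, targets[[b]], mcfg, cfg$loss)
        cls_l <- cls_l + ls$cls_loss / length(batch)
        reg_l <- reg_l + ls$reg_loss / length(batch)
        bw <- tpBackward(fw$tape, ls$seeds)
        if (is.null(grads)) {
          grads <- bw$param_grads
        } else {
          for (nm in names(bw$param_grads)) {
            grads[[nm]]$W <- grads[[nm]]$W + bw$param_grads[[nm]]$W
            grads[[nm]]$b <- grads[[nm]]$b + bw$param_grads[[nm]]$b
          }
        }
      }
      for (nm in names(grads)) {
        grads[[nm]]$W <- grads[[nm]]$W / length(batch)
        grads[[nm]]$b <- grads[[nm]]$b / length(batch)
      }
      st <- adamStep(model$params, grads, state, lr_t)
      model$params <- st$params
      state <- st$state
      total <- totalLoss(cls_l, reg_l)
      if (it == 1L || it == cfg$iterations || it %% cfg$log_every == 0L) {
        log[[length(log) + 1L]] <- data.frame(iteration = it, lr = lr_t,
                                              cls = cls_l, reg = reg_l,
                                              total = total)
        if (verbose)
          message(sprintf("iter %4d  lr %.2e  cls %.4f  reg %.4f  total %.4f",
                          it, lr_t, cls_l, reg_l, total))
      }
    }
  })
  model$stats <- stats
  model$fusion <- cfg$fusion
  model$colour_mode <- cfg$colour_mode
  model$class_names <- class_names
  model$run_config <- cfg
  model$log <- do.call(rbind, log)
  model
}

#' Detect objects in one scene
#'
#' Runs the trained front end (fusion arm, standardization, stride-32
#' padding) and the detector on a raw RGB scene, returning detections in
#' original image coordinates.
#'
#' @param model trained `"Detector"` (from [trainDetector()] or
#'   [loadCheckpoint()]).
#' @param pixels `H x W x 3` gamma sRGB array in `[0,1]`.
#' @param score_threshold optional override of the config threshold.
#' @return data.frame of detections (box columns, `class_id`, `score`,
#'   `class`).
#' @export
detectScene <- function(model, pixels, score_threshold = NULL) {
  if (is.null(model$fusion))
    model$fusion <- if (model$cfg$input_channels == 6L) "early_fusion" else "rgb"
  x <- buildNetworkInput(pixels, model$fusion,
                         if (is.null(model$colour_mode)) "srgb_linearized"
                         else model$colour_mode)
  prep <- prepareImage(x)
  if (!is.null(model$stats)) prep$image <- standardizeTensor(prep$image, model$stats)
  dets <- forwardDetect(model, prep$image, score_threshold = score_threshold,
                        record = prep$record)
  dets$class <- if (!is.null(model$class_names))
    model$class_names[dets$class_id] else as.character(dets$class_id)
  dets
}

#' Detect over image files
#'
#' @param model trained `"Detector"`.
#' @param paths character vector of PNG paths.
#' @param out optional path for a COCO-results style JSON
#'   (image_id, category_id, bbox, score).
#' @param score_threshold optional override.
#' @return data.frame of detections with an `image_id` column (the index
#'   into `paths`).
#' @export
detectImages <- function(model, paths, out = NULL, score_threshold = NULL) {
  res <- list()
  for (i in seq_along(paths)) {
    d <- detectScene(model, loadImageRGB(paths[i]), score_threshold)
    if (nrow(d) > 0L) d <- cbind(data.frame(image_id = i), d)
    res[[i]] <- d
  }
  res <- res[vapply(res, nrow, 0L) > 0L]
  dets <- if (length(res)) do.call(rbind, res) else
    data.frame(image_id = integer(0), x_min = numeric(0), y_min = numeric(0),
               x_max = numeric(0), y_max = numeric(0), class_id = integer(0),
               score = numeric(0), class = character(0))
  if (!is.null(out)) {
    recs <- lapply(seq_len(nrow(dets)), function(r) list(
      image_id = dets$image_id[r], category_id = dets$class_id[r],
      bbox = c(dets$x_min[r], dets$y_min[r], dets$x_max[r] - dets$x_min[r],
               dets$y_max[r] - dets$y_min[r]),
      score = dets$score[r]))
    jsonlite::write_json(recs, out, auto_unbox = TRUE, digits = NA)
  }
  dets
}

#' Evaluate a trained detector on annotated scenes
#'
#' Runs detection at a low score threshold (so AP can sweep the full
#' ranking), pools detections and ground truth across scenes, and applies
#' the evaluation protocol.
#'
#' @param model trained `"Detector"`.
#' @param scenes list of scenes as in [trainDetector()]; an optional
#'   `view` element per scene feeds the per-view breakdown.
#' @param protocol,score_threshold,interpolation see [evaluateRun()].
#' @return An `"EvalReport"`.
#' @export
evaluateDetector <- function(model, scenes, protocol = "standard",
                             score_threshold = NULL,
                             interpolation = "all_point") {
  if (length(scenes) == 0L) stop("empty validation set")
  if (is.null(score_threshold)) score_threshold <- model$cfg$score_threshold
  dets <- list(); gts <- list()
  for (i in seq_along(scenes)) {
    d <- detectScene(model, scenes[[i]]$pixels, score_threshold = 0.05)
    if (nrow(d) > 0L) dets[[length(dets) + 1L]] <- cbind(data.frame(image_id = i), d)
    g <- scenes[[i]]$annotations
    if (nrow(g) > 0L)
      gts[[length(gts) + 1L]] <- cbind(
        data.frame(image_id = i,
                   view = if (is.null(scenes[[i]]$view)) "V1" else
                     scenes[[i]]$view), g)
  }
  dets <- if (length(dets)) do.call(rbind, dets) else
    data.frame(image_id = integer(0), x_min = numeric(0), y_min = numeric(0),
               x_max = numeric(0), y_max = numeric(0), class_id = integer(0),
               score = numeric(0))
  gts <- do.call(rbind, gts)
  cn <- if (!is.null(model$class_names))
    setNames(model$class_names, seq_along(model$class_names)) else NULL
  evaluateRun(dets, gts, protocol = protocol,
              score_threshold = score_threshold,
              interpolation = interpolation, class_names = cn)
}

#' Calibrate the detection score threshold on annotated scenes
#'
#' Runs the detector once per scene at a low score floor, then evaluates F1
#' (IoU 0.5, pooled over scenes) for each candidate threshold and returns
#' the maximiser. Calibrating the operating point on the training (or a
#' validation) split is the standard way to pick a deployment threshold;
#' the held-out evaluation then uses the chosen value.
#'
#' @param model trained `"Detector"`.
#' @param scenes annotated scenes (training or validation split).
#' @param thresholds candidate score thresholds.
#' @param iou_thresh IoU used for matching during calibration.
#' @return list with `threshold` (the F1-maximising candidate) and `f1`
#'   (named vector of F1 per candidate).
#' @export
selectScoreThreshold <- function(model, scenes,
                                 thresholds = seq(0.2, 0.9, by = 0.05),
                                 iou_thresh = 0.5) {
  dets <- list(); gts <- list()
  for (i in seq_along(scenes)) {
    d <- detectScene(model, scenes[[i]]$pixels, score_threshold = 0.05)
    if (nrow(d) > 0L)
      dets[[length(dets) + 1L]] <- cbind(data.frame(image_id = i), d)
    g <- scenes[[i]]$annotations
    if (nrow(g) > 0L) gts[[length(gts) + 1L]] <- cbind(data.frame(image_id = i), g)
  }
  dets <- if (length(dets)) do.call(rbind, dets) else
    data.frame(image_id = integer(0), x_min = numeric(0), y_min = numeric(0),
               x_max = numeric(0), y_max = numeric(0), class_id = integer(0),
               score = numeric(0))
  gts <- do.call(rbind, gts)
  f1s <- vapply(thresholds, function(thr) {
    m <- matchDetections(dets[dets$score >= thr, , drop = FALSE], gts,
                         iou_thresh)
    unname(precisionRecallF1(m)["F1"])
  }, 0)
  names(f1s) <- format(thresholds)
  list(threshold = thresholds[which.max(f1s)], f1 = f1s)
}

#' Per-channel colour visualisation panels
#'
#' Converts an RGB image to CIELab and returns each channel normalised to
#' `[0,1]` for display, alongside the RGB channels — the front end's six
#' network inputs.
#'
#' @param pixels `H x W x 3` gamma sRGB array.
#' @param mode see [rgbToXyz()].
#' @return named list of `H x W` matrices: R, G, B, L, a, b.
#' @export
colourPanels <- function(pixels, mode = "srgb_linearized") {
  lab <- pixels(rgbToLab(ColourImage(pixels), mode = mode))
  list(R = pixels[, , 1], G = pixels[, , 2], B = pixels[, , 3],
       L = lab[, , 1] / 100,
       a = (lab[, , 2] + 128) / 255,
       b = (lab[, , 3] + 128) / 255)
}
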