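# Detector plumbing: pyramid stride arithmetic, anchors, box coding,
# target assignment, head shapes, and inference-time decoding.

small_cfg <- function(...) modelConfig(input_channels = 6L,
                                       backbone_width = 8L,
                                       fpn_channels = 16L, head_depth = 2L,
                                       ...)

test_that("pyramid shapes follow ceil-halving stride arithmetic", {
  sh <- pyramidShapes(736, 1280)
  expect_equal(sh$F3, c(92, 160))
  expect_equal(sh$F4, c(46, 80))
  expect_equal(sh$F5, c(23, 40))
  expect_equal(sh$F6, c(12, 20))
  expect_equal(sh$F7, c(6, 10))
})

test_that("anchor count is A * sum(Hl*Wl) for arbitrary pyramid shapes", {
  cfg <- modelConfig()
  shapes <- list(c(4, 4), c(2, 2), c(1, 1))
  anch <- generateAnchors(shapes, cfg, levels = 3:5)
  expect_equal(nrow(anch), 9 * (16 + 4 + 1))
  set.seed(11)
  for (i in 1:20) {
    h <- sample(33:600, 1); w <- sample(33:600, 1)
    sh <- pyramidShapes(h, w)
    anch <- generateAnchors(sh, cfg)
    expect_equal(nrow(anch),
                 cfg$anchors_per_location *
                   sum(vapply(sh, function(s) s[1] * s[2], 0)))
  }
  expect_error(generateAnchors(list(), cfg), "empty")
})

test_that("anchors are square at ratio 1:1 and grid-spaced by the stride", {
  cfg <- modelConfig()
  anch <- generateAnchors(list(c(4, 4)), cfg, levels = 3L)
  w <- anch$x_max - anch$x_min
  h <- anch$y_max - anch$y_min
  expect_true(all(w > 0 & h > 0))
  # ratio ordering: scales fastest, ratios slowest; middle 3 anchors are 1:1
  ratio1 <- which(abs(w / h - 1) < 1e-6)
  expect_equal(length(ratio1), 3 * 16)
  cx <- sort(unique(round((anch$x_min + anch$x_max) / 2, 9)))
  expect_equal(diff(cx), rep(8, 3)) # level-3 stride
})

test_that("box coding closed forms and exact round trip", {
  a <- data.frame(x_min = 10, y_min = 20, x_max = 30, y_max = 40)
  expect_equal(as.numeric(encodeBoxes(a, a)), c(0, 0, 0, 0))
  wide <- data.frame(x_min = 0, y_min = 20, x_max = 40, y_max = 40)
  expect_equal(encodeBoxes(a, wide)[1, "tw"], log(2), tolerance = 1e-12,
               ignore_attr = TRUE)
  set.seed(12)
  anch <- data.frame(x_min = runif(50, 0, 50), y_min = runif(50, 0, 50))
  anch$x_max <- anch$x_min + runif(50, 5, 30)
  anch$y_max <- anch$y_min + runif(50, 5, 30)
  gt <- data.frame(x_min = runif(50, 0, 50), y_min = runif(50, 0, 50))
  gt$x_max <- gt$x_min + runif(50, 5, 30)
  gt$y_max <- gt$y_min + runif(50, 5, 30)
  dec <- decodeBoxes(anch, encodeBoxes(anch, gt))
  expect_equal(as.matrix(dec), as.matrix(gt), tolerance = 1e-6,
               ignore_attr = TRUE)
  # zero offsets decode to the anchors themselves
  dec0 <- decodeBoxes(anch, matrix(0, 50, 4))
  expect_equal(as.matrix(dec0), as.matrix(anch), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(encodeBoxes(a, data.frame(x_min = 5, y_min = 5, x_max = 5,
                                         y_max = 10)), "positive")
})

test_that("anchor assignment applies the positive/ignore/background bands", {
  cfg <- modelConfig()
  anch <- data.frame(x_min = c(0, 0, 50), y_min = c(0, 0, 50),
                     x_max = c(10, 12, 60), y_max = c(10, 10, 60))
  gt <- data.frame(x_min = 0, y_min = 0, x_max = 10, y_max = 10,
                   class_id = 2L)
  t <- assignTargets(anch, gt)
  expect_equal(t$labels[1], 2L)          # IoU 1 -> positive
  expect_equal(t$labels[3], 0L)          # disjoint -> background
  expect_equal(iou(anch[2, ], gt), 10 / 12, tolerance = 1e-12)
  expect_equal(t$labels[2], 2L)
  # an anchor whose best IoU lands in [0.4, 0.5) is ignored
  mid <- data.frame(x_min = 0, y_min = 0, x_max = 10, y_max = 22)
  t2 <- assignTargets(mid, gt)
  expect_equal(iou(mid, gt), 100 / 220, tolerance = 1e-12)
  expect_equal(t2$labels, -1L)
  # no ground truth: everything background
  t3 <- assignTargets(anch, gt[0, ])
  expect_true(all(t3$labels == 0L))
  expect_error(assignTargets(anch, gt, pos_iou = 0.3, neg_iou = 0.4),
               "exceed")
})

test_that("backbone and heads produce the documented shapes", {
  cfg <- small_cfg()
  m <- buildDetector(cfg, seed = 5)
  x <- array(0.1, c(64, 64, 6))
  fw <- strawdetect:::detectorForward(m, x)
  dims <- vapply(fw$levels, function(l) dim(l$cls)[1], 0)
  expect_equal(dims, c(8, 4, 2, 1, 1))
  for (lv in fw$levels) {
    expect_equal(dim(lv$cls)[3], cfg$num_classes * cfg$anchors_per_location)
    expect_equal(dim(lv$reg)[3], 4 * cfg$anchors_per_location)
  }
  expect_error(strawdetect:::detectorForward(m, array(0, c(60, 64, 6))),
               "divisible by 32")
  expect_error(strawdetect:::detectorForward(m, array(0, c(64, 64, 3))),
               "depth")
  expect_error(modelConfig(input_channels = 4), "3 or 6")
  m3 <- buildDetector(modelConfig(input_channels = 3, backbone_width = 8,
                                  fpn_channels = 16, head_depth = 1),
                      seed = 5)
  fw3 <- strawdetect:::detectorForward(m3, array(0.1, c(64, 64, 3)))
  expect_equal(length(fw3$levels), 5)
})

test_that("zero input isolates the head biases (linearity of the stack)", {
  m <- buildDetector(small_cfg(), seed = 6)
  fw <- strawdetect:::detectorForward(m, array(0, c(64, 64, 6)))
  expect_true(all(abs(fw$levels[[1]]$reg) < 1e-12))
  cls_bias <- m$params$clsout$b[1]
  expect_true(all(abs(fw$levels[[1]]$cls - cls_bias) < 1e-9))
})

test_that("prior-probability bias makes the untrained detector quiet", {
  m <- buildDetector(small_cfg(), seed = 7)
  x <- array(runif(64 * 64 * 6), c(64, 64, 6))
  fw <- strawdetect:::detectorForward(m, x)
  scores <- unlist(lapply(fw$levels, function(l) 1 / (1 + exp(-l$cls))))
  expect_gte(mean(scores), 0.005)
  expect_lte(mean(scores), 0.02)
  dets <- forwardDetect(m, x, score_threshold = 0.3)
  expect_equal(nrow(dets), 0)
})

test_that("sub-net weights are shared across pyramid levels", {
  m <- buildDetector(small_cfg(), seed = 8)
  # feed the same feature map through the classification tower twice on
  # separate tape nodes; outputs must agree exactly
  f <- array(rnorm(4 * 4 * 16), c(4, 4, 16))
  tp <- strawdetect:::newTape(m$params)
  i1 <- strawdetect:::tpInput(tp, f)
  i2 <- strawdetect:::tpInput(tp, f)
  o1 <- strawdetect:::tpConv(tp, i1, "cls1")
  o2 <- strawdetect:::tpConv(tp, i2, "cls1")
  expect_identical(tp$vals[[o1]], tp$vals[[o2]])
})

test_that("detections are deterministic and monotone in the score threshold", {
  m <- buildDetector(small_cfg(prior_prob = 0.35), seed = 9)
  x <- array(runif(64 * 64 * 6), c(64, 64, 6))
  d1 <- forwardDetect(m, x, score_threshold = 0.3)
  d2 <- forwardDetect(m, x, score_threshold = 0.3)
  expect_identical(d1, d2)
  n <- vapply(c(0.5, 0.4, 0.3, 0.2), function(thr)
    nrow(forwardDetect(m, x, score_threshold = thr)), 0L)
  expect_true(all(diff(n) >= 0))
})

test_that("anchor base factor 3 covers the generated berry sizes; 4 does not", {
  spec <- sceneSpec()
  best_iou <- function(bf) {
    cfg <- modelConfig(anchor_base_factor = bf)
    anch <- generateAnchors(pyramidShapes(128, 128), cfg)
    unlist(lapply(1:10, function(i) {
      sc <- generateScene(spec, seed = 5000 + i)
      apply(iouMatrix(anch, sc$annotations), 2, max)
    }))
  }
  expect_true(all(best_iou(3) >= 0.5))   # every gt can become a positive
  expect_lt(mean(best_iou(4) >= 0.5), 1) # the default base leaves gaps here
})

test_that("stem inflation preserves the response to duplicated channels", {
  m3 <- buildDetector(modelConfig(input_channels = 3, backbone_width = 8,
                                  fpn_channels = 16, head_depth = 1), seed = 2)
  m6 <- buildDetector(modelConfig(input_channels = 6, backbone_width = 8,
                                  fpn_channels = 16, head_depth = 1), seed = 3)
  m6 <- inflateStemChannels(m6, m3$params$stem)
  # a 6-channel input that duplicates a 3-channel one excites the inflated
  # stem exactly as the original stem sees the 3-channel input
  x3 <- array(runif(32 * 32 * 3), c(32, 32, 3))
  x6 <- array(c(x3, x3), c(32, 32, 6))
  s3 <- strawdetect:::cpp_conv_fw(x3, m3$params$stem$W, m3$params$stem$b,
                                  7L, 7L, 2L, 3L)$out
  s6 <- strawdetect:::cpp_conv_fw(x6, m6$params$stem$W, m6$params$stem$b,
                                  7L, 7L, 2L, 3L)$out
  expect_equal(s6, s3, tolerance = 1e-12)
  expect_error(inflateStemChannels(m3, m3$params$stem), "6 input channels")
})

test_that("checkpoints round-trip the model and its detections", {
  m <- buildDetector(small_cfg(prior_prob = 0.3), seed = 10)
  m$class_names <- c("ripe", "unripe")
  m$fusion <- "early_fusion"
  m$stats <- channelStats(rep(0, 6), rep(1, 6))
  path <- tempfile(fileext = ".rds")
  saveCheckpoint(m, path)
  m2 <- loadCheckpoint(path)
  expect_equal(m2$cfg$input_channels, 6L)
  x <- array(runif(64 * 64 * 6), c(64, 64, 6))
  expect_identical(forwardDetect(m, x, 0.25), forwardDetect(m2, x, 0.25))
})
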