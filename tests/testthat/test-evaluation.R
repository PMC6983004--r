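# Evaluation protocol: IoU, NMS, greedy matching, P/R/F1, AP, FP curves.

test_that("IoU basic identities and the 1/3 overlap case", {
  a <- c(0, 0, 10, 10)
  expect_equal(iou(a, a), 1)
  expect_equal(iou(a, c(20, 20, 30, 30)), 0)
  b <- c(5, 0, 15, 10)
  expect_equal(iou(a, b), 1 / 3, tolerance = 1e-12)
  expect_equal(iou(a, b), oracle_iou_pixelcount(a, b), tolerance = 1e-12)
  expect_error(iou(a, c(5, 5, 5, 10)), "degenerate")
})

test_that("IoU is symmetric, bounded, 1 iff identical (random integer boxes)", {
  set.seed(31)
  for (i in 1:200) {
    inst <- random_instance(2, 0)
    a <- as.numeric(inst$dets[1, 1:4]); b <- as.numeric(inst$dets[2, 1:4])
    v <- iou(a, b)
    expect_equal(v, iou(b, a))
    expect_gte(v, 0); expect_lte(v, 1)
    expect_equal(v, oracle_iou_pixelcount(a, b), tolerance = 1e-12)
    if (v == 1) expect_equal(a, b)
  }
})

test_that("NMS matches the brute-force reference and is idempotent", {
  set.seed(32)
  inst <- random_instance(200, 0, K = 2, size = 40)
  dets <- inst$dets
  out <- nms(dets, 0.5)
  kept_ref <- oracle_nms(dets, 0.5)
  key <- function(d) sort(paste(d$x_min, d$y_min, d$x_max, d$y_max, d$class_id,
                                d$score))
  expect_identical(key(out), key(dets[kept_ref, ]))
  expect_identical(key(nms(out, 0.5)), key(out))
  # two identical boxes: higher score survives; disjoint boxes both survive
  two <- data.frame(x_min = c(0, 0), y_min = c(0, 0), x_max = c(10, 10),
                    y_max = c(10, 10), class_id = 1L, score = c(0.9, 0.8))
  expect_equal(nms(two, 0.5)$score, 0.9)
  two$x_min[2] <- 50; two$x_max[2] <- 60
  expect_equal(nrow(nms(two, 0.5)), 2)
  expect_error(nms(two, 0), "thresh")
})

test_that("greedy matching enforces one match per gt and class agreement", {
  gt <- data.frame(x_min = 0, y_min = 0, x_max = 10, y_max = 10, class_id = 1L)
  dets <- data.frame(x_min = c(0, 1), y_min = c(0, 0), x_max = c(10, 10),
                     y_max = c(10, 10), class_id = 1L, score = c(0.9, 0.8))
  m <- matchDetections(dets, gt, 0.5)
  expect_equal(c(m$TP, m$FP, m$FN), c(1, 1, 0))
  # class must match even at high IoU
  wrong <- data.frame(x_min = 0.5, y_min = 0, x_max = 10, y_max = 10,
                      class_id = 2L, score = 0.95)
  m2 <- matchDetections(wrong, gt, 0.5)
  expect_equal(c(m2$TP, m2$FP, m2$FN), c(0, 1, 1))
})

test_that("matching, P/R/F1 and AP agree with exhaustive oracles", {
  set.seed(33)
  for (i in 1:120) {
    inst <- random_instance(sample(0:20, 1), sample(0:10, 1))
    m <- matchDetections(inst$dets, inst$gts, 0.5)
    ref <- oracle_match(inst$dets, inst$gts, 0.5)
    expect_equal(c(m$TP, m$FP, m$FN), c(ref$TP, ref$FP, ref$FN))
    prf <- precisionRecallF1(m)
    P <- if (ref$TP + ref$FP > 0) ref$TP / (ref$TP + ref$FP) else 0
    R <- if (ref$TP + ref$FN > 0) ref$TP / (ref$TP + ref$FN) else 0
    expect_equal(unname(prf["P"]), P)
    expect_equal(unname(prf["R"]), R)
    if (nrow(inst$gts) > 0) {
      ap <- averagePrecision(inst$dets, inst$gts, 0.5)
      for (cls in names(ap$per_class)) {
        ref_ap <- oracle_ap_class(
          inst$dets[inst$dets$class_id == as.integer(cls), , drop = FALSE],
          inst$gts[inst$gts$class_id == as.integer(cls), , drop = FALSE], 0.5)
        expect_equal(unname(ap$per_class[cls]), ref_ap, tolerance = 1e-9)
      }
    }
  }
})

test_that("P/R/F1 closed-form cases and bounds", {
  expect_equal(unname(precisionRecallF1(1, 1, 1)), c(0.5, 0.5, 0.5))
  prf <- precisionRecallF1(2, 1, 2)
  expect_equal(unname(prf), c(2 / 3, 1 / 2, 4 / 7))
  expect_equal(unname(precisionRecallF1(0, 0, 0)), c(0, 0, 0))
  set.seed(34)
  for (i in 1:50) {
    prf <- precisionRecallF1(sample(0:9, 1), sample(0:9, 1), sample(0:9, 1))
    expect_gte(prf["F1"], min(prf["P"], prf["R"]) - 1e-12)
    expect_lte(prf["F1"], max(prf["P"], prf["R"]) + 1e-12)
  }
})

test_that("AP handles the canonical small cases and score rescaling", {
  gt <- data.frame(x_min = 0, y_min = 0, x_max = 10, y_max = 10, class_id = 1L)
  one <- data.frame(x_min = 0, y_min = 0, x_max = 10, y_max = 10,
                    class_id = 1L, score = 0.7)
  expect_equal(averagePrecision(one, gt, 0.5)$mean, 1.0)
  # FP ranked above the TP: precision at full recall is 1/2
  two <- rbind(data.frame(x_min = 50, y_min = 50, x_max = 60, y_max = 60,
                          class_id = 1L, score = 0.9), one)
  expect_equal(averagePrecision(two, gt, 0.5)$mean, 0.5)
  # AP invariant to monotone score rescaling
  two2 <- two; two2$score <- two2$score^3 / 2
  expect_equal(averagePrecision(two2, gt, 0.5)$mean,
               averagePrecision(two, gt, 0.5)$mean)
  # 11-point variant also available
  expect_equal(averagePrecision(one, gt, 0.5,
                                interpolation = "eleven_point")$mean, 1.0)
})

test_that("FP decomposition curves are ordered and hit the fixed points", {
  gt <- data.frame(image_id = 1, x_min = c(0, 30), y_min = c(0, 30),
                   x_max = c(10, 40), y_max = c(10, 40), class_id = c(1L, 2L))
  perfect <- data.frame(image_id = 1, x_min = c(0, 30), y_min = c(0, 30),
                        x_max = c(10, 40), y_max = c(10, 40),
                        class_id = c(1L, 2L), score = c(0.9, 0.8))
  pc <- fpAnalysis(perfect, gt)
  expect_equal(vapply(unclass(pc), `[[`, 0, "area"),
               c(C50 = 1, C40 = 1, LOC = 1, SIM = 1, CLS = 1, BGR = 1,
                 FIN = 1))
  # correct box, wrong class: C50 < CLS = 1 for the one-object case
  one_gt <- gt[1, ]
  wrong_cls <- data.frame(image_id = 1, x_min = 0.5, y_min = 0, x_max = 10,
                          y_max = 10, class_id = 2L, score = 0.9)
  pc2 <- fpAnalysis(wrong_cls, one_gt)
  expect_lt(pc2$C50$area, pc2$CLS$area)
  expect_equal(pc2$CLS$area, 1) # removing the cross-class FP leaves no error
  expect_equal(pc2$SIM$area, 1) # both classes share the supercategory
  # constructed mixture of loc/cls/background errors keeps the ordering
  set.seed(35)
  for (i in 1:20) {
    inst <- random_instance(15, 8)
    inst$dets$image_id <- 1; inst$gts$image_id <- 1
    areas <- vapply(unclass(fpAnalysis(inst$dets, inst$gts)), `[[`, 0, "area")
    expect_true(all(diff(areas) >= -1e-9))
    expect_equal(unname(areas["FIN"]), 1)
  }
})

test_that("evaluateRun applies both protocols' thresholds correctly", {
  # one detection at IoU ~0.45: counts under the 0.4 protocol, not 0.5
  gt <- data.frame(image_id = 1, view = "V1", x_min = 0, y_min = 0,
                   x_max = 10, y_max = 10, class_id = 1L)
  det <- data.frame(image_id = 1, x_min = 0, y_min = 0, x_max = 10,
                    y_max = 22, class_id = 1L, score = 0.95)
  expect_equal(iou(det[, 2:5], gt[, 3:6]), 100 / 220, tolerance = 1e-12)
  std <- evaluateRun(det, gt, protocol = "standard", score_threshold = 0.5)
  df <- evaluateRun(det, gt, protocol = "deepfruits")
  g <- function(rep) rep$table[rep$table$view_group == "overall" &
                                 rep$table$class == "mean", ]
  expect_equal(g(std)$TP, 0)
  expect_equal(g(df)$TP, 1)
  # deepfruits drops scores <= 0.9
  det$score <- 0.85
  df2 <- evaluateRun(det, gt, protocol = "deepfruits")
  expect_equal(g(df2)$TP + g(df2)$FP, 0)
  # empty detections: P = R = F1 = 0
  none <- det[0, ]
  e <- evaluateRun(none, gt)
  expect_equal(unlist(g(e)[c("P", "R", "F1")]), c(P = 0, R = 0, F1 = 0))
  # mismatched image ids are rejected
  bad <- det; bad$image_id <- 99
  expect_error(evaluateRun(bad, gt), "image ids")
})

test_that("evaluateRun reports per view group and both classes", {
  set.seed(36)
  gts <- do.call(rbind, lapply(1:6, function(i) {
    inst <- random_instance(0, 3)
    cbind(data.frame(image_id = i, view = c("V1", "V2", "V3")[(i - 1) %% 3 + 1]),
          inst$gts)
  }))
  dets <- cbind(gts[c("image_id", "x_min", "y_min", "x_max", "y_max",
                      "class_id")],
                data.frame(score = runif(nrow(gts), 0.91, 0.99)))
  rep <- evaluateRun(dets, gts, protocol = "standard", score_threshold = 0.5)
  expect_setequal(unique(rep$table$view_group), c("overall", "V1", "V2-3"))
  ov <- rep$table[rep$table$view_group == "overall", ]
  expect_true(all(ov$F1 == 1) && all(ov$AP == 1) && all(ov$P == 1))
})
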