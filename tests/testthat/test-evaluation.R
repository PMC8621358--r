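box <- function(x1, y1, x2, y2, conf = NA_real_, cat = NA_character_,
                img = "img") {
  b <- box_annotations(x1, y1, x2, y2, confidence = conf, category = cat)
  b$image_id <- img
  b
}

test_that("box IoU matches the pixel-enumeration oracle", {
  a <- box(0, 0, 10, 10)
  expect_equal(box_iou(a, a), 1)
  expect_equal(box_iou(a, box(20, 20, 30, 30)), 0)
  expect_equal(box_iou(a, box(5, 0, 15, 10)), 50 / 150)
  expect_error(box_iou(a, list(xmin = 3, ymin = 3, xmax = 3, ymax = 9)),
               "degenerate")
  set.seed(17)
  for (trial in 1:25) {
    p <- random_boxes(1); q <- random_boxes(1)
    expect_equal(box_iou(p, q), oracle_box_iou(p, q), tolerance = 1e-12)
  }
})

test_that("greedy matching honours confidence order and one-to-one-ness", {
  gt <- box(0, 0, 10, 10)
  m <- match_detections(box(0, 0, 10, 10, conf = 0.9), gt)
  expect_equal(c(m$TP, m$FP, m$FN), c(1, 0, 0))
  # two predictions compete for the same ground truth
  preds <- box(c(0, 0), c(0, 1), c(10, 10), c(9, 10), conf = c(0.9, 0.8))
  m2 <- match_detections(preds, gt)
  expect_equal(c(m2$TP, m2$FP), c(1, 1))
  expect_equal(m2$matches$pred, 1)   # higher confidence wins the match
  # no predictions: all ground truths are misses
  m3 <- match_detections(box_annotations(), box(c(0, 11, 22), c(0, 0, 0),
                                                c(10, 21, 32), c(10, 10, 10)))
  expect_equal(c(m3$TP, m3$FP, m3$FN), c(0, 0, 3))
  # a spike-free image with no predictions is one true negative
  m4 <- match_detections(box_annotations(), box_annotations())
  expect_equal(m4$TN, 1)
  # predictions without confidence are rejected
  expect_error(match_detections(box(0, 0, 5, 5), gt), "confidence")
  # matching never assigns a ground truth twice
  set.seed(5)
  for (trial in 1:20) {
    p <- random_boxes(6); g <- random_boxes(4, conf = FALSE)
    mm <- match_detections(p, g, 0.3)
    expect_false(any(duplicated(mm$matches$gt)))
    expect_equal(mm$TP + mm$FN, nrow(g))
    expect_equal(mm$TP + mm$FP, nrow(p))
  }
})

test_that("precision/recall/accuracy/F1 reproduce the published worked counts", {
  # full-resolution detector counts: 119 hits, 3 false alarms, 125 spikes
  s <- detection_scores(list(TP = 119, FP = 3, FN = 6, TN = 0))
  expect_equal(unname(s["P"]), 119 / 122, tolerance = 1e-12)
  expect_equal(unname(s["R"]), 0.952, tolerance = 1e-12)
  expect_equal(unname(s["F1"]),
               2 * (119 / 122) * 0.952 / (119 / 122 + 0.952), tolerance = 1e-12)
  expect_warning(s0 <- detection_scores(list(TP = 0, FP = 0, FN = 5, TN = 0)),
                 "precision undefined")
  expect_true(is.nan(s0["P"]))
  expect_equal(unname(s0["R"]), 0)
  expect_true(is.nan(s0["F1"]))
  s1 <- detection_scores(list(TP = 10, FP = 0, FN = 0, TN = 2))
  expect_equal(unname(s1["A"]), 1.0)
})

test_that("the 11-point AP matches the hand-worked examples", {
  gt1 <- box(0, 0, 10, 10)
  expect_equal(ap_11point(box(0, 0, 10, 10, conf = 0.8), gt1), 1.0)
  # only false positives
  expect_equal(ap_11point(box(50, 50, 60, 60, conf = 0.8), gt1), 0.0)
  # 2 GTs, one TP at conf 0.9 then one FP at conf 0.8: AP = 6/11
  gts <- box(c(0, 20), c(0, 20), c(10, 30), c(10, 30))
  preds <- box(c(0, 50), c(0, 50), c(10, 60), c(10, 60), conf = c(0.9, 0.8))
  expect_equal(ap_11point(preds, gts), 6 / 11, tolerance = 1e-12)
  expect_error(ap_11point(preds, box_annotations()), "zero ground truths")
})

test_that("the COCO sweep uses 10 thresholds and the 101-point interpolation", {
  gts <- box(c(0, 20), c(0, 20), c(10, 30), c(10, 30))
  perfect <- box(c(0, 20), c(0, 20), c(10, 30), c(10, 30), conf = c(0.9, 0.8))
  res <- ap_coco(perfect, gts)
  expect_length(res$ap_per_threshold, 10)
  expect_equal(res$thresholds, seq(0.5, 0.95, by = 0.05))
  expect_equal(unname(res$ap_per_threshold), rep(1, 10))
  expect_equal(res$mean_ap, 1)
  # all predictions at IoU exactly 0.6 with their GT: thresholds 0.5-0.6 pass
  shifted <- box(c(0, 20), c(0 + 2.5, 20 + 2.5), c(10, 30),
                 c(10 + 2.5, 30 + 2.5), conf = c(0.9, 0.8))
  iou <- box_iou(shifted[1, ], gts[1, ])
  expect_equal(iou, 0.6, tolerance = 1e-12)
  res2 <- ap_coco(shifted, gts)
  expect_equal(res2$mean_ap, 3 / 10, tolerance = 1e-12)
})

test_that("AP agrees with the brute-force cutoff-sweep oracle", {
  set.seed(1234)
  for (trial in 1:60) {
    np <- sample(0:6, 1); ng <- sample(1:4, 1)
    preds <- random_boxes(np)
    gts <- random_boxes(ng, conf = FALSE)
    thr <- sample(c(0.3, 0.5, 0.7), 1)
    expect_equal(ap_11point(preds, gts, thr),
                 oracle_ap(preds, gts, thr, seq(0, 1, 0.1)),
                 tolerance = 1e-10, label = paste("11pt trial", trial))
    expect_equal(ap_coco(preds, gts)$ap_per_threshold[["0.50"]],
                 oracle_ap(preds, gts, 0.5, seq(0, 1, 0.01)),
                 tolerance = 1e-10, label = paste("coco trial", trial))
  }
})

test_that("AP is invariant to monotone confidence transforms and FP-append-safe", {
  set.seed(55)
  for (trial in 1:10) {
    preds <- random_boxes(5)
    gts <- random_boxes(3, conf = FALSE)
    ap0 <- ap_11point(preds, gts)
    mono <- preds
    mono$confidence <- plogis(3 * mono$confidence - 1)   # strictly increasing
    expect_equal(ap_11point(mono, gts), ap0, tolerance = 1e-12)
    # appending a disjoint false positive at the lowest confidence
    worse <- rbind(preds, box(90, 90, 99, 99,
                              conf = min(preds$confidence) / 2)[,
                                                                names(preds)])
    expect_lte(ap_11point(worse, gts), ap0 + 1e-12)
  }
})

test_that("mean AP averages over classes", {
  expect_equal(mean_ap(0.8), 0.8)
  expect_equal(mean_ap(c(0.6, 1.0)), 0.8)
  expect_equal(mean_ap(rep(0.37, 5)), 0.37)
  expect_error(mean_ap(numeric()), "empty")
})

test_that("mask metrics match pixel counts and the Dice/Jaccard identity", {
  m <- matrix(0L, 30, 30); m[5:14, 5:14] <- 1L
  all1 <- mask_metrics(m, m)
  expect_equal(unname(all1), rep(1, 5))
  disj <- matrix(0L, 30, 30); disj[16:25, 16:25] <- 1L
  d0 <- mask_metrics(m, disj)
  expect_equal(unname(d0["dice"]), 0)
  expect_equal(unname(d0["jaccard"]), 0)
  # |P| = |G| = 100, overlap 50
  half <- matrix(0L, 30, 30); half[5:14, 10:19] <- 1L
  dh <- mask_metrics(m, half)
  expect_equal(unname(dh["dice"]), 0.5)
  expect_equal(unname(dh["jaccard"]), 50 / 150)
  expect_error(mask_metrics(m, matrix(0L, 10, 10)), "shapes")
  # dice >= jaccard and dice = 2j/(1+j) on random masks
  set.seed(8)
  for (trial in 1:20) {
    a <- matrix(rbinom(400, 1, 0.3), 20, 20)
    b <- matrix(rbinom(400, 1, 0.3), 20, 20)
    mm <- mask_metrics(a, b)
    expect_gte(mm["dice"], mm["jaccard"])
    expect_equal(unname(mm["dice"]),
                 2 * mm[["jaccard"]] / (1 + mm[["jaccard"]]),
                 tolerance = 1e-12)
  }
})

test_that("category-stratified evaluation attributes counts to GT categories", {
  gts <- box(c(0, 20), c(0, 0), c(10, 30), c(10, 10), cat = "top")
  preds <- box(c(0, 20), c(0, 0), c(10, 30), c(10, 10), conf = c(0.9, 0.8))
  rep1 <- evaluate_by_category(preds, gts)
  expect_equal(rep1$category, "top")
  expect_equal(rep1$ap_11point, 1.0)
  expect_equal(rep1$mean_tp_confidence, 0.85)
  # 2 top detected, 1 occluded missed
  gts2 <- box(c(0, 20, 40), c(0, 0, 0), c(10, 30, 50), c(10, 10, 10),
              cat = c("top", "top", "occluded_emergent"))
  rep2 <- evaluate_by_category(preds, gts2)
  top <- rep2[rep2$category == "top", ]
  occ <- rep2[rep2$category == "occluded_emergent", ]
  expect_equal(top$recall, 1.0)
  expect_equal(occ$recall, 0.0)
  expect_equal(occ$TP, 0)
  # missing tags are an error
  bad <- gts2; bad$category[2] <- NA
  expect_error(evaluate_by_category(preds, bad), "category")
})
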