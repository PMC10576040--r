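test_that("iou handles the standard cases", {
  expect_equal(iou(c(0.5, 0.5, 0.2, 0.2), c(0.5, 0.5, 0.2, 0.2)), 1.0)
  expect_equal(iou(c(0.2, 0.2, 0.1, 0.1), c(0.8, 0.8, 0.1, 0.1)), 0.0)
  expect_equal(iou(c(0, 0, 2, 2), c(1, 1, 3, 3), form = "corner"), 1 / 7)
  expect_error(iou(c(0, 0, -1, 1), c(0, 0, 1, 1)), "negative")
})

test_that("nms keeps the winner, spares disjoint boxes and is idempotent", {
  d <- data.frame(cx = c(0.5, 0.52, 0.9), cy = c(0.5, 0.5, 0.9),
                  w = c(0.2, 0.2, 0.1), h = c(0.2, 0.2, 0.1),
                  conf = c(0.9, 0.8, 0.7), class = 0L)
  kept <- nms(d, iou_threshold = 0.5, conf_threshold = 0.25)
  expect_identical(nrow(kept), 2L)
  expect_equal(kept$conf, c(0.9, 0.7))
  expect_equal(nms(kept, 0.5, 0.25), kept, ignore_attr = TRUE)
  # different classes are never suppressed against each other
  d2 <- d[1:2, ]; d2$class <- c(0L, 1L)
  expect_identical(nrow(nms(d2, 0.5, 0.25)), 2L)
  expect_identical(nrow(nms(d[0, ], 0.5, 0.25)), 0L)
})

test_that("greedy matching yields the contracted TP/FP/FN counts", {
  gt <- data.frame(image = 1L, class = 0L, cx = 0.5, cy = 0.5,
                   w = 0.2, h = 0.2)
  d1 <- data.frame(image = 1L, class = 0L, cx = 0.52, cy = 0.5,
                   w = 0.2, h = 0.2, conf = 0.9)
  m <- match_detections(d1, gt, 0.5)
  expect_identical(sum(m$tp), 1L)
  expect_identical(m$fn, 0L)
  expect_equal(m$precision[1], 1)
  expect_equal(m$recall[1], 1)
  # no detections: all ground truths are misses
  m0 <- match_detections(d1[0, ], rbind(gt, gt, gt), 0.5)
  expect_identical(m0$fn, 3L)
  # two detections on one gt: second is a FP
  d2 <- rbind(d1, transform(d1, conf = 0.8))
  m2 <- match_detections(d2, gt, 0.5)
  expect_identical(m2$tp, c(TRUE, FALSE))
  expect_equal(m2$precision[2], 0.5)
  expect_equal(m2$recall[2], 1)
})

test_that("average precision follows the enveloped all-point integral", {
  gt <- data.frame(image = 1L, class = 0L, cx = 0.5, cy = 0.5,
                   w = 0.2, h = 0.2)
  tp <- data.frame(image = 1L, class = 0L, cx = 0.5, cy = 0.5,
                   w = 0.2, h = 0.2, conf = 0.9)
  fp <- data.frame(image = 1L, class = 0L, cx = 0.1, cy = 0.1,
                   w = 0.05, h = 0.05, conf = 0.8)
  expect_equal(average_precision(match_detections(tp, gt, 0.5)), 1.0)
  # TP then FP: recall 1 reached before the FP -> AP 1
  expect_equal(average_precision(match_detections(rbind(tp, fp), gt, 0.5)),
               1.0)
  # FP first (higher confidence): envelope constant 0.5 -> AP 0.5
  fp$conf <- 0.95
  expect_equal(average_precision(match_detections(rbind(fp, tp), gt, 0.5)),
               0.5)
  # zero ground truths: undefined, not zero
  expect_true(is.na(average_precision(match_detections(tp, gt[0, ], 0.5))))
})

test_that("mAP reduces over classes and thresholds as specified", {
  gt <- data.frame(image = 1L, class = c(0L, 1L),
                   cx = c(0.3, 0.7), cy = c(0.3, 0.7), w = 0.2, h = 0.2)
  # class 0 matched perfectly; class 1: FP first then TP -> AP 0.5
  dets <- data.frame(image = 1L, class = c(0L, 1L, 1L),
                     cx = c(0.3, 0.1, 0.7), cy = c(0.3, 0.1, 0.7),
                     w = c(0.2, 0.2, 0.2), h = c(0.2, 0.2, 0.2),
                     conf = c(0.9, 0.95, 0.8))
  ev <- mean_average_precision(dets, gt, 0.5)
  expect_equal(unname(ev$per_class[, 1]), c(1.0, 0.5))
  expect_equal(ev$map, 0.75)
  # single class: mAP == AP
  ev0 <- mean_average_precision(dets[dets$class == 0L, ],
                                gt[gt$class == 0L, ], 0.5)
  expect_equal(ev0$map, 1.0)
})

test_that("AP equals the cutoff-enumeration oracle on random scenes", {
  set.seed(99)
  for (i in 1:100) {
    sc <- random_scene_pair()
    for (cl in unique(sc$gts$class)) {
      d <- sc$dets[sc$dets$class == cl, , drop = FALSE]
      g <- sc$gts[sc$gts$class == cl, , drop = FALSE]
      ap <- average_precision(match_detections(d, g, 0.5))
      expect_equal(ap, oracle_ap(d, g, 0.5), tolerance = 1e-9)
    }
  }
})

test_that("raising the IoU threshold never increases AP; ranged <= mAP@0.5", {
  set.seed(123)
  for (i in 1:20) {
    sc <- random_scene_pair()
    aps <- vapply(seq(0.5, 0.95, 0.05), function(t)
      mean_average_precision(sc$dets, sc$gts, t)$map, numeric(1))
    expect_true(all(diff(aps) <= 1e-12))
    ranged <- mean_average_precision(sc$dets, sc$gts,
                                     seq(0.5, 0.95, 0.05))$map
    expect_lte(ranged, aps[1] + 1e-12)
  }
})

test_that("mAP is invariant to detection row order under the tie-break", {
  set.seed(7)
  sc <- random_scene_pair()
  ev1 <- mean_average_precision(sc$dets, sc$gts, 0.5)
  perm <- sample(nrow(sc$dets))
  ev2 <- mean_average_precision(sc$dets[perm, ], sc$gts, 0.5)
  expect_equal(ev1$map, ev2$map)
})

test_that("ground truth evaluated against itself scores a perfect mAP", {
  set.seed(8)
  sc <- random_scene_pair()
  self <- cbind(sc$gts, conf = 1.0)
  ev <- mean_average_precision(self, sc$gts, 0.5)
  expect_equal(ev$map, 1.0)
  expect_equal(ev$recall, 1.0)
})
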