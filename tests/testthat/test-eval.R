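det_on <- function(b, conf) detection(b, conf)

test_that("match_detections implements one-to-one greedy matching", {
  gt <- box(10, 10, 20, 20)
  m1 <- match_detections(list(det_on(gt, 0.9)), list(gt))
  expect_identical(m1$counts[c("TP", "FP", "FN")],
                   list(TP = 1L, FP = 0L, FN = 0L))
  expect_true(is.na(m1$counts$TN))
  # two detections on one ground truth: only the first (by confidence) is TP
  m2 <- match_detections(list(det_on(gt, 0.9), det_on(gt, 0.8)), list(gt))
  expect_identical(m2$counts[c("TP", "FP", "FN")],
                   list(TP = 1L, FP = 1L, FN = 0L))
  expect_identical(m2$flags, c(TRUE, FALSE))
  # detection below the IOU threshold is FP and the gt FN
  m3 <- match_detections(list(det_on(box(0, 0, 5, 5), 0.9)), list(gt))
  expect_identical(m3$counts[c("TP", "FP", "FN")],
                   list(TP = 0L, FP = 1L, FN = 1L))
  # class-aware: wrong label never matches
  m4 <- match_detections(list(detection(gt, 0.9, "rbc")), list(gt))
  expect_identical(m4$counts$TP, 0L)
})

test_that("matching counts equal the independent reference on random scenes", {
  set.seed(71)
  for (rep in 1:50) {
    sc <- random_scene(n_gt = sample(0:6, 1), n_det = sample(0:12, 1))
    got <- match_detections(sc$dets, sc$gts, eval_iou = 0.5)$counts
    ref <- oracle_match(sc$dets, sc$gts, 0.5)
    expect_identical(got[c("TP", "FP", "FN")], ref)
  }
})

test_that("precision / recall / F1 formulas and conventions", {
  counts <- list(TP = 8L, FP = 2L, FN = 4L)
  expect_equal(precision(counts), 0.8)
  expect_equal(recall(counts), 8 / 12)
  expect_equal(f1(counts), 2 * 8 / (2 * 8 + 2 + 4))
  # the two F1 forms agree exactly, including the TP=FP=FN case -> 1/2
  eq <- list(TP = 3L, FP = 3L, FN = 3L)
  expect_identical(f1(eq), 0.5)
  expect_identical(f1(p = precision(eq), r = recall(eq)), 0.5)
  set.seed(73)
  for (i in 1:50) {
    c0 <- list(TP = sample(0:20, 1), FP = sample(0:20, 1),
               FN = sample(0:20, 1))
    p <- precision(c0); r <- recall(c0)
    if (p + r > 0) expect_equal(f1(c0), 2 * p * r / (p + r), tolerance = 1e-12)
  }
  zero <- list(TP = 0L, FP = 0L, FN = 0L)
  expect_identical(precision(zero), 0)
  expect_identical(recall(zero), 0)
  expect_identical(f1(zero), 0)
})

test_that("average precision: examples and the prefix-enumeration oracle", {
  # single correct detection over a single gt
  expect_identical(average_precision(pr_curve(TRUE, 1)), 1)
  # ranked [TP, FP] over 1 gt: all recall gained at precision 1
  expect_identical(average_precision(pr_curve(c(TRUE, FALSE), 1)), 1)
  # ranked [FP, TP] over 1 gt: recall gained at precision 1/2
  expect_identical(average_precision(pr_curve(c(FALSE, TRUE), 1)), 0.5)
  expect_warning(v <- average_precision(pr_curve(logical(0), 0)), "zero")
  expect_identical(v, 0)
  set.seed(79)
  for (rep in 1:100) {
    n <- sample(1:30, 1)
    flags <- runif(n) < 0.4
    n_gt <- max(sum(flags), sample(1:10, 1))
    curve <- pr_curve(flags, n_gt)
    expect_equal(average_precision(curve), oracle_ap(flags, n_gt),
                 tolerance = 1e-12)
    # curve invariants
    expect_true(all(diff(curve$recall) >= 0))
    expect_true(all(curve$precision >= 0 & curve$precision <= 1))
    expect_equal(sum(curve$delta_recall), curve$recall[n], tolerance = 1e-12)
  }
})

test_that("AP is 1 iff every gt is recalled before any false positive", {
  expect_identical(average_precision(pr_curve(c(TRUE, TRUE, FALSE), 2)), 1)
  expect_lt(average_precision(pr_curve(c(TRUE, FALSE, TRUE), 2)), 1)
})

test_that("threshold_sweep recomputes each operating point consistently", {
  set.seed(83)
  scenes <- lapply(1:5, function(i) random_scene(n_gt = 4, n_det = 10))
  dets <- lapply(scenes, function(s) s$dets)
  gts <- lapply(scenes, function(s) s$gts)
  sw <- threshold_sweep(dets, gts, thresholds = seq(0, 1, 0.1))
  # recall is non-increasing in the threshold
  expect_true(all(diff(sw$recall) <= 1e-12))
  # a threshold above every confidence yields zero recall
  expect_identical(sw$recall[sw$threshold == 1], 0)
  # per-row recomputation oracle
  for (r in seq_len(nrow(sw))) {
    kept <- lapply(dets, function(dd) {
      Filter(function(d) d$confidence >= sw$threshold[r], dd)
    })
    ev <- evaluate_detections(kept, gts)
    expect_identical(sw$TP[r], ev$counts$TP)
    expect_equal(sw$f1[r], ev$f1, tolerance = 1e-12)
  }
  expect_true(attr(sw, "best_threshold") %in% sw$threshold)
  expect_equal(max(sw$f1), sw$f1[sw$threshold == attr(sw, "best_threshold")])
})

test_that("precision rises along a constructed monotone fixture", {
  # confidences aligned with correctness: high-conf TPs, low-conf FPs
  gt <- random_boxes(5, size = 50)
  dets <- c(lapply(seq_along(gt), function(i) detection(gt[[i]], 0.9 - i * 0.02)),
            lapply(1:5, function(i) detection(box(100 + 3 * i, 100, 104 + 3 * i, 104),
                                              0.3 - i * 0.02)))
  sw <- threshold_sweep(list(dets), list(gt), thresholds = c(0.1, 0.5))
  expect_gt(sw$precision[2], sw$precision[1])
})

test_that("comparison_report emits one row per run with consistent F1", {
  runs <- list(
    improved = list(ap = 0.8731, f1 = 0.88, precision = 0.8906,
                    recall = 0.8731, time_s = 4.07),
    baseline = list(ap = 0.8420, f1 = 0.86, precision = 0.8531,
                    recall = 0.8686, time_s = 2.85))
  df <- comparison_report(runs)
  expect_identical(nrow(df), 2L)
  expect_identical(df$method, c("improved", "baseline"))
  # report F1 always matches f1(P, R) of the same row to rounding
  for (r in seq_len(nrow(df))) {
    expect_equal(df$F1[r], 100 * f1(p = df$precision[r] / 100,
                                    r = df$recall[r] / 100),
                 tolerance = 1)
  }
  path <- withr::local_tempfile(fileext = ".tsv")
  comparison_report(runs, path)
  back <- utils::read.delim(path)
  expect_identical(nrow(back), 2L)
  expect_equal(back$AP, df$AP, tolerance = 1e-6)
})
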